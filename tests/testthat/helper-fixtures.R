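# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, spec) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, generate_fixture(spec, outdir = tempfile(name)),
           envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the default desk-scale fixture used across unit tests
default_fixture <- function() cached_fixture("default", fixture_spec(seed = 42))

# a larger mixed-strand fixture for oracle-equivalence checks
medium_fixture <- function() {
  cached_fixture("medium", fixture_spec(
    seed = 202, n_chromosomes = 3, n_mirnas = 60, fraction_minus_strand = 0.5,
    n_seed_variants = 40, n_mature_variants = 40, n_precursor_variants = 40,
    n_outside_variants = 20, n_planted_dnps = 4, n_planted_mnp_runs = 2,
    n_planted_seed_switches = 5, n_qtl = 30, n_fragile_sites = 10,
    n_host_genes = 9
  ))
}

# parse the on-disk files of a fixture back through the io layer
parse_fixture <- function(fx) {
  mirna <- read_mirna_gff(fx$paths$gff, fasta = fx$paths$fasta)
  variants <- read_vcf(fx$paths$vcf)
  list(mirna = mirna, variants = variants)
}
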