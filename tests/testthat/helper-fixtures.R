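# Shared small fixtures, built once per test run (helpers are sourced before
# the test files). Sizes are kept small so the whole suite stays fast; the
# acceptance file builds its own full-size fixture.

small_genome <- refscaf::generate_genome(c(20000, 12000), seed = 101)

# Clean fragmentation (no inversions, no mutations) of the small genome.
small_clean <- refscaf::fragment_genome(
  small_genome, n_contigs = 8, gap_mean = 300, inversion_prob = 0,
  mutation_rate = 0, seed = 102)

# Divergent draft: inversions + 1% mutations + contaminants.
small_draft <- refscaf::fragment_genome(
  small_genome, n_contigs = 8, gap_mean = 300, inversion_prob = 0.4,
  mutation_rate = 0.01, n_contaminants = 2, seed = 103)

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

record <- function(id, seq) {
  data.frame(id = id, description = "", sequence = seq,
             stringsAsFactors = FALSE)
}
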