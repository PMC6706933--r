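# Small in-code fixtures shared across test files.

# A hand-sized screen: 4 guides, 2 genes, one control + one treated sample.
tiny_screen <- function() {
  screen_counts(
    guide_id = c("gA_1", "gA_2", "gB_1", "gB_2"),
    gene = c("geneA", "geneA", "geneB", "geneB"),
    counts = matrix(c(100, 200, 300, 400,
                      110, 180, 320, 390),
                    ncol = 2, dimnames = list(NULL, c("CTRL", "DRUG"))),
    control_samples = "CTRL", treated_samples = "DRUG"
  )
}

# Write a tab-delimited count table and return its path.
write_tiny_table <- function(path = tempfile(fileext = ".txt"),
                             lines = NULL) {
  if (is.null(lines)) {
    lines <- c("GUIDE\tGENE\tCTRL\tDRUG",
               "gA_1\tgeneA\t100\t110",
               "gA_2\tgeneA\t200\t180",
               "gB_1\tgeneB\t300\t320",
               "gB_2\tgeneB\t400\t390")
  }
  writeLines(lines, path)
  path
}

# Null screen: treated and control arms are exchangeable NB resamples.
null_sim <- function(seed, n_genes = 1000) {
  simulate_screen(sim_config(n_genes = n_genes, frac_synergy = 0,
                             frac_suppressor = 0, fitness_frac = 0,
                             seed = seed))
}
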