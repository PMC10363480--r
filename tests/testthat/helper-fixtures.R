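# Shared helpers: packaged fixtures and seeded random peptides.

fig1_path <- function() {
  system.file("extdata", "fig1_peptides_synthetic.fasta",
              package = "chimeraTP", mustWork = TRUE)
}

grid_path <- function() {
  system.file("extdata", "fig2_grid.tsv", package = "chimeraTP",
              mustWork = TRUE)
}

AA20 <- chimeraTP:::AA20

# One random peptide string (uniform over the 20 residues).
random_seq <- function(len) paste(sample(AA20, len, replace = TRUE),
                                  collapse = "")

# A seeded set of random peptides with lengths drawn in [min_len, max_len].
random_peptides <- function(n, min_len = 10, max_len = 50, seed = 1) {
  chimeraTP:::withSeed(seed, {
    lens <- min_len + sample.int(max_len - min_len + 1L, n,
                                 replace = TRUE) - 1L
    PeptideSet(stats::setNames(vapply(lens, random_seq, character(1)),
                               sprintf("rand_%04d", seq_len(n))))
  })
}

write_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
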