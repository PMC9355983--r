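# fixture builders shared across test files

make_matrix <- function(genes, samples, values, kind = "raw") {
  m <- matrix(values, nrow = length(genes),
              dimnames = list(genes, samples))
  expression_matrix(m, kind)
}

random_counts <- function(n_genes, n_samples, seed, mu = 100, size = 10) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
              nrow = n_genes,
              dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  expression_matrix(m, "raw")
}

tiny_signature <- function(n_up = 3, n_down = 2) {
  gene_signature(sprintf("UP%d", seq_len(n_up)),
                 sprintf("DN%d", seq_len(n_down)), name = "tiny")
}

# two-timepoint growth table with explicit volumes (width/length dummies
# consistent with nothing; volume column takes precedence downstream)
two_day_growth <- function(vol_by_animal, groups, days = c(0, 21)) {
  rows <- list()
  for (id in names(vol_by_animal)) {
    v <- vol_by_animal[[id]]
    rows[[id]] <- data.frame(animal_id = id, group = groups[[id]],
                             day = days, width = 1, length = 1,
                             volume = v, stringsAsFactors = FALSE)
  }
  as_growth_table(do.call(rbind, rows))
}
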