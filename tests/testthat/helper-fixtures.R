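# Shared fixture builders: everything is generated in code at test time.

random_counts <- function(n_genes = 50, n_samples = 4, seed = 1, mean = 50) {
  set.seed(seed)
  matrix(rpois(n_genes * n_samples, mean), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# A tiny hand-buildable sparse cell matrix covering all marker genes.
toy_cells <- function(counts, labels = NULL) {
  if (is.null(labels)) labels <- setNames(rep("Tumor", ncol(counts)), colnames(counts))
  sparse_cell_matrix(counts, labels)
}

marker_matrix <- function(...) {
  # rows fixed to the rule genes; columns given as named vectors per cell
  cells <- list(...)
  genes <- c("GLI1", "GLI2", "GLI3", "STAT1", "IRF1", "IDO1")
  m <- sapply(cells, function(v) {
    row <- setNames(numeric(length(genes)), genes)
    row[names(v)] <- v
    row
  })
  rownames(m) <- genes
  colnames(m) <- sprintf("c%02d", seq_along(cells))
  m
}
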