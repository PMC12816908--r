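# Small in-code fixtures shared across test files.

tiny_expr <- function(values = NULL, n_genes = 5, n_samples = 4,
                      value_class = "continuous", seed = 42) {
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(if (value_class == "count") rpois(n_genes * n_samples, 5)
                     else rnorm(n_genes * n_samples),
                     n_genes, n_samples)
  }
  dimnames(values) <- list(sprintf("g%02d", seq_len(nrow(values))),
                           sprintf("s%02d", seq_len(ncol(values))))
  expression_matrix(values, value_class = value_class)
}

# Deterministic toy cell dataset with an obvious malignant-up, score-linked gene.
tiny_cell_dataset <- function(n_cells = 30, n_genes = 12, seed = 7) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_cells, 4), n_genes, n_cells,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   sprintf("c%02d", seq_len(n_cells))))
  mal <- rep(c(TRUE, FALSE), length.out = n_cells)
  types <- ifelse(mal, "malignant", "immune")
  cell_dataset(expression_matrix(counts, value_class = "count"),
               types, mal, "toy")
}

# Six-patient survival fixture with a fully worked log-rank oracle in tests.
six_patient_surv <- function() {
  survival_table(data.frame(
    patient = paste0("p", 1:6),
    time = c(5, 8, 12, 6, 10, 15),
    event = c(1, 1, 0, 1, 0, 1),
    stage = c(2, 3, 1, 4, 2, 1)))
}

six_patient_scores <- function() {
  stats::setNames(c(3, 2.5, 2, 1, 0.5, 0), paste0("p", 1:6))
}

# Independent log-rank oracle: explicit observed-minus-expected summation.
logrank_oracle <- function(time, event, in_group1) {
  ev_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    nj <- sum(at_risk); n1j <- sum(at_risk & in_group1)
    dj <- sum(time == t & event == 1)
    d1j <- sum(time == t & event == 1 & in_group1)
    O <- O + d1j
    E <- E + dj * n1j / nj
    if (nj > 1) V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  (O - E)^2 / V
}
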