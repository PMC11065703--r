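# Independent brute-force oracles and tiny fixture builders used across tests.
# Each oracle is a literal transcription of the defining formula, kept free of
# any code path it is used to check.

# Recovery-curve AUC by explicit enumeration: walk ranks 1..max_rank, count
# set genes seen so far, accumulate the curve, normalise by the top-packed
# maximum.
oracle_auc <- function(rank_of_set_genes, n_genes, k_total, max_rank) {
  y <- vapply(seq_len(max_rank),
              function(i) sum(rank_of_set_genes <= i), numeric(1))
  raw <- sum(y)
  max_area <- sum(pmin(seq_len(max_rank), k_total))
  if (k_total == 0) 0 else raw / max_area
}

# Rank-biserial via all-pairs counting: (#{x>y} - #{x<y}) / (n1*n2).
oracle_rank_biserial <- function(x, y) {
  gt <- sum(outer(x, y, ">"))
  lt <- sum(outer(x, y, "<"))
  (gt - lt) / (length(x) * length(y))
}

# Exact two-sided Wilcoxon p by full enumeration over all C(n1+n2, n1)
# group labelings of the pooled sample (no ties assumed).
oracle_exact_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# DerSimonian-Laird pooling transcribed directly from its defining equations.
oracle_dl <- function(g, se) {
  k <- length(g)
  w <- 1 / se^2
  gf <- sum(w * g) / sum(w)
  Q <- sum(w * (g - gf)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / C)
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * g) / sum(wr)
  se_p <- sqrt(1 / sum(wr))
  list(tau2 = tau2, pooled = pooled, se = se_p,
       i2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0)
}

# Small deterministic expression dataset: expression value encodes a known
# per-cell ordering so rankings are predictable.
tiny_dataset <- function(n_genes = 10, n_cells = 4, normalised = FALSE) {
  m <- sapply(seq_len(n_cells), function(j) rev(seq_len(n_genes)) * j)
  rownames(m) <- paste0("g", seq_len(n_genes))
  colnames(m) <- paste0("c", seq_len(n_cells))
  meta <- tibble::tibble(cell_id = colnames(m), sample_id = "s1",
                         diagnosis = "NDC", cell_type = "Micro")
  expression_dataset(m, rownames(m), colnames(m), meta,
                     normalised = normalised)
}

# Minimal imaging table: cells on a grid in one ROI with the given channels.
tiny_imaging_table <- function(n = 6, channels = list(Iba1 = 10, GLB1 = 1),
                               roi_id = "roi1", sample_id = "s1") {
  df <- tibble::tibble(
    cell_id = paste0("c", seq_len(n)), roi_id = roi_id,
    sample_id = sample_id, diagnosis = "AD", region = "other",
    x_um = seq(10, 10 * n, by = 10), y_um = 25, cluster_label = "Micro")
  for (ch in names(channels)) df[[ch]] <- rep_len(channels[[ch]], n)
  as_imaging_cell_table(df, channels = names(channels))
}
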