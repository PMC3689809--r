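# Worked four-gene example: FPKM values at pre, 3, 10, 30, 60 min and the
# fold-change columns as printed in the source study's summary table.
table3_fpkm <- function() {
  time_course_matrix(rbind(
    GLOD4   = c(3.55, 8.10, 12.50, 15.05, 11.58),
    NXN     = c(4.22, 16.29, 88.76, 190.26, 246.42),
    SPATA4  = c(11.99, 94.49, 163.70, 111.98, 28.03),
    ZMYND10 = c(4.08, 36.79, 117.92, 34.19, 0.71)))
}

table3_printed_fold <- function() {
  m <- rbind(
    GLOD4   = c(2.28, 3.52, 4.24, 3.26),
    NXN     = c(3.86, 21.03, 45.07, 58.38),
    SPATA4  = c(7.88, 13.65, 9.34, 2.34),
    ZMYND10 = c(9.02, 28.92, 8.38, 0.17))
  colnames(m) <- c("r3", "r10", "r30", "r60")
  m
}

write_table3_tsv <- function(path = tempfile(fileext = ".tsv")) {
  m <- table3_fpkm()
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Random row-stochastic membership matrix
random_membership <- function(n, k) {
  u <- matrix(runif(n * k), n, k)
  u / rowSums(u)
}

# Independent oracle for the membership cutoff: plain enumeration over the
# distinct membership values, counting per-gene assignments with a loop.
cutoff_oracle <- function(u) {
  vals <- sort(unique(as.vector(u)))
  score <- vapply(vals, function(t) {
    abs(mean(apply(u, 1L, function(row) sum(row >= t))) - 1)
  }, numeric(1))
  vals[which.min(score)]
}

# Independent oracle for single-linkage merging: connected components of the
# graph joining centroid pairs with Pearson correlation > merge_r (BFS).
components_oracle <- function(centroids, merge_r) {
  q <- nrow(centroids)
  adj <- cor(t(centroids)) > merge_r
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, q)
  cur <- 0L
  for (s in seq_len(q)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      i <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[i])) next
      comp[i] <- cur
      queue <- c(queue, which(adj[i, ] & is.na(comp)))
    }
  }
  split(rownames(centroids), comp)
}

# Compare two partitions given as lists of member vectors, order-free
same_partition <- function(a, b) {
  canon <- function(p) {
    p <- lapply(p, sort)
    p[order(vapply(p, `[`, character(1), 1L))]
  }
  isTRUE(all.equal(unname(canon(a)), unname(canon(b))))
}
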