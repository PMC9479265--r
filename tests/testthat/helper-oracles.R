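# Independent oracles, deliberately written without the package's
# internals: exhaustive scans and direct formula transcriptions.

# O(n*m) exhaustive nearest-outlet scan, chunked to bound memory.
# Ties at equal squared distance resolve to the lowest outlet_id,
# matching the documented tie-break.
oracle_nearest <- function(fixes, outlets, chunk = 2000L) {
  o <- outlets[order(outlets$outlet_id), , drop = FALSE]
  n <- nrow(fixes)
  id <- character(n)
  dist <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    i <- start:min(start + chunk - 1L, n)
    d2 <- outer(fixes$x[i], o$x, "-")^2 + outer(fixes$y[i], o$y, "-")^2
    j <- apply(d2, 1L, which.min) # first minimum = lowest id after sort
    id[i] <- o$outlet_id[j]
    dist[i] <- sqrt(d2[cbind(seq_along(i), j)])
  }
  list(outlet_id = id, distance = dist)
}

# direct transcription of the stratified between-cluster linearization
# variance of a weighted mean (single-stratum designs exercise nh > 1)
oracle_weighted_mean <- function(x, w, strata, clusters) {
  m <- sum(w * x) / sum(w)
  e <- w * (x - m) / sum(w)
  v <- 0
  for (h in unique(strata)) {
    zh <- tapply(e[strata == h], clusters[strata == h], sum)
    nh <- length(zh)
    v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  list(mean = m, se = sqrt(v))
}

# small deterministic outlet grid for geometry tests
toy_outlets <- function() {
  tibble::tibble(
    outlet_id = c("O01", "O02", "O03", "O04"),
    licence = c("on_sales", "off_sales", "on_sales", "off_sales"),
    x = c(0, 100, 0, 250),
    y = c(0, 0, 200, 250))
}
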