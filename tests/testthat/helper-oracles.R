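# ---- brute-force least-squares oracle -------------------------------------
# Hand-built effect-coded design matrices and type-III F via nested RSS
# comparisons; independent of the model-fitting path under test.
effect_code <- function(f) {
  lev <- sort(unique(as.character(f)))
  k <- length(lev)
  X <- matrix(0, length(f), k - 1)
  for (j in seq_len(k - 1)) {
    X[f == lev[j], j] <- 1
    X[f == lev[k], j] <- -1
  }
  X
}

oracle_f_tests <- function(data, response, f1, f2, covariate = NULL) {
  y <- data[[response]]
  G <- effect_code(data[[f1]])
  C <- effect_code(data[[f2]])
  GC <- do.call(cbind, lapply(seq_len(ncol(G)), function(i) {
    sweep(C, 1, G[, i], `*`)
  }))
  blocks <- list(G, C, GC)
  names(blocks) <- c(f1, f2, paste0(f1, ":", f2))
  if (!is.null(covariate)) blocks[[covariate]] <- matrix(data[[covariate]])
  X_full <- cbind(1, do.call(cbind, blocks))
  rss <- function(X) sum(qr.resid(qr(X), y)^2)
  rss_full <- rss(X_full)
  df_res <- nrow(X_full) - ncol(X_full)
  out <- list()
  for (nm in names(blocks)) {
    X_red <- cbind(1, do.call(cbind, blocks[setdiff(names(blocks), nm)]))
    q <- ncol(blocks[[nm]])
    out[[nm]] <- ((rss(X_red) - rss_full) / q) / (rss_full / df_res)
  }
  out
}

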