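# Independent reference implementations used as oracles. Deliberately naive
# (per-pair / per-edge / per-fold loops over base-R primitives) and kept
# separate from the package's vectorized code paths.

# Pearson FC by explicit double loop over node pairs
oracle_fc <- function(ts) {
  n <- ncol(ts)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    x <- ts[, i] - mean(ts[, i])
    y <- ts[, j] - mean(ts[, j])
    out[i, j] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  out
}

# single-edge association: cor.test for plain Pearson, lm-residual partial
# correlation with df = n - 2 - k otherwise
oracle_edge_assoc <- function(e, y, X = NULL) {
  if (is.null(X)) {
    ct <- stats::cor.test(e, y)
    list(r = unname(ct$estimate), p = ct$p.value)
  } else {
    re <- stats::resid(stats::lm(e ~ X))
    ry <- stats::resid(stats::lm(y ~ X))
    r <- stats::cor(re, ry)
    df <- length(y) - 2 - ncol(X)
    tt <- r * sqrt(df / (1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(tt), df))
  }
}

# naive fold-by-fold LOOCV: re-select with cor.test/lm per edge, re-fit with
# lm, predict the held-out subject from the coefficients
oracle_loocv <- function(E, y, X = NULL, threshold = 0.01,
                         aggregate = "sum") {
  n <- nrow(E)
  p <- ncol(E)
  pred <- matrix(NA_real_, n, 3,
                 dimnames = list(NULL, c("positive", "negative", "combined")))
  masks <- vector("list", n)
  agg <- function(idx, rows) {
    if (length(idx) == 0) return(rep(0, length(rows)))
    s <- rowSums(E[rows, idx, drop = FALSE])
    if (aggregate == "mean") s / length(idx) else s
  }
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    rs <- ps <- numeric(p)
    for (j in seq_len(p)) {
      st <- oracle_edge_assoc(E[tr, j], y[tr],
                              if (is.null(X)) NULL else X[tr, , drop = FALSE])
      rs[j] <- st$r
      ps[j] <- st$p
    }
    pos <- which(ps < threshold & rs > 0)
    neg <- which(ps < threshold & rs < 0)
    sp <- agg(pos, tr)
    sn <- agg(neg, tr)
    mu <- mean(y[tr])
    fit1 <- function(s) if (stats::var(s) == 0) c(mu, 0)
    else unname(stats::coef(stats::lm(y[tr] ~ s)))
    cp <- fit1(sp)
    cn <- fit1(sn)
    if (stats::var(sp) > 0 && stats::var(sn) > 0) {
      cc <- unname(stats::coef(stats::lm(y[tr] ~ sp + sn)))
    } else if (stats::var(sp) > 0) {
      cc <- c(cp, 0)
    } else if (stats::var(sn) > 0) {
      cc <- c(cn[1], 0, cn[2])
    } else cc <- c(mu, 0, 0)
    spi <- agg(pos, i)
    sni <- agg(neg, i)
    pred[i, ] <- c(cp[1] + cp[2] * spi,
                   cn[1] + cn[2] * sni,
                   cc[1] + cc[2] * spi + cc[3] * sni)
    masks[[i]] <- list(positive = pos, negative = neg)
  }
  list(predictions = pred, masks = masks)
}

# brute-force per-edge network summary
oracle_summarize <- function(mask, atlas) {
  nets <- canonical_networks()
  n <- (1 + sqrt(1 + 8 * length(mask))) / 2
  cm <- matrix(0L, length(nets), length(nets), dimnames = list(nets, nets))
  deg <- integer(n)
  tot <- stats::setNames(integer(length(nets)), nets)
  k <- 0L
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    k <- k + 1L
    if (!mask[k]) next
    a <- atlas$network[atlas$node_id == i]
    b <- atlas$network[atlas$node_id == j]
    cm[a, b] <- cm[a, b] + 1L
    if (a != b) cm[b, a] <- cm[b, a] + 1L
    deg[i] <- deg[i] + 1L
    deg[j] <- deg[j] + 1L
    tot[a] <- tot[a] + 1L
    if (b != a) tot[b] <- tot[b] + 1L
  }
  list(count_matrix = cm, per_network_total = tot, per_node_degree = deg)
}

# small synthetic dataset shorthand used across test files; planted-edge
# defaults scale down on tiny atlases
make_sim <- function(seed, n_subjects = 100, n_nodes = 25, effect_r = 0.4,
                     ...) {
  extra <- list(...)
  n_e <- n_nodes * (n_nodes - 1) / 2
  if (is.null(extra$n_pos_edges)) extra$n_pos_edges <- min(20, n_e %/% 5)
  if (is.null(extra$n_neg_edges)) extra$n_neg_edges <- min(20, n_e %/% 5)
  do.call(generator_config,
          c(list(n_subjects = n_subjects, n_nodes = n_nodes,
                 effect_r = effect_r, seed = seed), extra)) |>
    generate_dataset()
}
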