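#' Pseudobulk time-course matrix
#'
#' Summarizes each gene as its mean log-normalized expression over the
#' selected cells of each of the five ordered groups, then z-scores each
#' gene across the 5 values (mean 0, sd 1) so that trajectory shapes are
#' comparable across expression magnitudes. Genes constant across groups
#' cannot be z-scored and are dropped with a warning.
#'
#' @param norm log-normalized matrix.
#' @param ann annotation aligned to `norm`.
#' @param cell_type_filter keep only cells of these types (NULL = all).
#' @param gene_filter restrict to these genes (NULL = all).
#' @return list: `raw` (gene x 5 group means), `z` (z-scored rows,
#'   constant rows removed).
#' @export
pseudobulk_timecourse <- function(norm, ann, cell_type_filter = NULL,
                                  gene_filter = NULL) {
  stopifnot(identical(colnames(norm), rownames(ann)))
  keep <- rep(TRUE, ncol(norm))
  if (!is.null(cell_type_filter)) keep <- ann$cell_type %in% cell_type_filter
  if (!any(keep)) stop("no cells after cell-type filtering")
  sub <- norm[, keep, drop = FALSE]
  grp <- ann$group[keep]
  if (!is.null(gene_filter)) {
    genes <- intersect(gene_filter, rownames(sub))
    if (length(genes) == 0) stop("empty gene filter")
    sub <- sub[genes, , drop = FALSE]
  }
  missing <- setdiff(group_levels(), as.character(unique(grp)))
  if (length(missing) > 0) {
    stop("group(s) absent from data: ", paste(missing, collapse = ", "))
  }
  raw <- sapply(group_levels(), function(g)
    Matrix::rowMeans(sub[, grp == g, drop = FALSE]))
  raw <- matrix(raw, ncol = 5, dimnames = list(rownames(sub), group_levels()))
  mu <- rowMeans(raw)
  sdv <- apply(raw, 1, sd)
  const <- sdv <= .Machine$double.eps * 10
  if (any(const)) {
    warning(sum(const), " gene(s) constant across groups dropped from z-scored matrix")
  }
  z <- (raw[!const, , drop = FALSE] - mu[!const]) / sdv[!const]
  list(raw = raw, z = z)
}

#' Fuzzy c-means co-expression modules
#'
#' Standard fuzzy c-means on the z-scored group trajectories: memberships
#' `u(g,k) = 1 / sum_l (||x_g - c_k|| / ||x_g - c_l||)^(2/(m-1))`, centroids
#' `c_k = sum_g u^m x_g / sum_g u^m`, objective `J = sum u^m d^2`. The
#' alternating updates make J non-increasing; the best of `restarts` seeded
#' random initializations (centroids drawn from the data rows) is kept. A
#' gene landing exactly on a centroid gets membership 1 there.
#'
#' @param tc a [pseudobulk_timecourse()] result (its `z` matrix is used) or
#'   a plain numeric matrix of trajectories.
#' @param k number of modules (default 6).
#' @param m fuzzifier (> 1; default 2).
#' @param seed RNG seed for initialization.
#' @param restarts random restarts (default 20).
#' @param tol convergence tolerance on the relative change of J.
#' @param max_iter iteration cap per restart.
#' @return list of class `fcm_result`: `membership` (genes x k), `label`
#'   (hard argmax assignment), `centroids` (k x columns), `objective`
#'   (final J), `objective_trace` (J per iteration of the winning restart).
#' @export
fuzzy_cmeans <- function(tc, k = 6, m = 2.0, seed = 1, restarts = 20,
                         tol = 1e-6, max_iter = 500) {
  x <- if (is.list(tc)) tc$z else tc
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k = ", k, " exceeds number of genes (", n, ")")
  stopifnot(m > 1)
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, r))
    init <- x[sample.int(n, k), , drop = FALSE]
    fit <- fcm_run(x, init, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  rownames(best$membership) <- rownames(x)
  names(best$label) <- rownames(x)
  colnames(best$centroids) <- colnames(x)
  structure(c(best, list(k = k, m = m)), class = "fcm_result")
}

fcm_membership <- function(d2, m) {
  # d2: n x k squared distances
  exact <- d2 < .Machine$double.eps
  u <- 1 / (d2^(1 / (m - 1)))
  u <- u / rowSums(u)
  hit <- which(rowSums(exact) > 0)
  if (length(hit) > 0) {
    u[hit, ] <- 0
    u[cbind(hit, max.col(-d2[hit, , drop = FALSE]))] <- 1
  }
  u
}

fcm_run <- function(x, centroids, m, tol, max_iter) {
  sq_dist <- function(cts) {
    # n x k matrix of squared distances
    outer(rowSums(x^2), rep(1, nrow(cts))) - 2 * x %*% t(cts) +
      outer(rep(1, nrow(x)), rowSums(cts^2))
  }
  d2 <- pmax(sq_dist(centroids), 0)
  u <- fcm_membership(d2, m)
  J <- sum(u^m * d2)
  trace <- J
  for (it in seq_len(max_iter)) {
    um <- u^m
    centroids <- (t(um) %*% x) / colSums(um)
    d2 <- pmax(sq_dist(centroids), 0)
    u <- fcm_membership(d2, m)
    J_new <- sum(u^m * d2)
    trace <- c(trace, J_new)
    if (abs(J - J_new) <= tol * max(J, .Machine$double.eps)) {
      J <- J_new
      break
    }
    J <- J_new
  }
  list(membership = u, label = max.col(u), centroids = centroids,
       objective = J, objective_trace = trace)
}

#' Label a centroid's temporal trend
#'
#' Consecutive group-to-group steps of the 5-point trajectory are
#' thresholded at `epsilon` into +/0/-: `development_up` means non-negative
#' steps T1->T3 with at least one positive; `t3_peak` additionally requires
#' negative steps on T3->T4 and T4->T5; `aging_down` means a negative
#' T4->T5 step. Flags are non-exclusive; the primary label follows the
#' precedence t3_peak > development_up > aging_down > flat. The rule is a
#' labeling convention of this package (the epsilon applies to z-scored
#' trajectories).
#'
#' @param centroid numeric 5-vector (T1..T5).
#' @param epsilon step threshold on the z scale (default 0.1).
#' @return list: `flags` (character vector) and `primary` (single label).
#' @export
classify_trend <- function(centroid, epsilon = 0.1) {
  stopifnot(length(centroid) == 5)
  s <- diff(centroid)
  sgn <- ifelse(s > epsilon, 1L, ifelse(s < -epsilon, -1L, 0L))
  flags <- character(0)
  dev_up <- all(sgn[1:2] >= 0) && any(sgn[1:2] == 1)
  if (dev_up) flags <- c(flags, "development_up")
  if (dev_up && all(sgn[3:4] == -1)) flags <- c(flags, "t3_peak")
  if (sgn[4] == -1) flags <- c(flags, "aging_down")
  primary <- if ("t3_peak" %in% flags) "t3_peak"
  else if ("development_up" %in% flags) "development_up"
  else if ("aging_down" %in% flags) "aging_down"
  else "flat"
  list(flags = flags, primary = primary)
}

#' Trend labels for every centroid of a clustering
#'
#' @param fit [fuzzy_cmeans()] result.
#' @param epsilon see [classify_trend()].
#' @return data.frame: module, primary, flags (comma-separated).
#' @export
label_modules <- function(fit, epsilon = 0.1) {
  labs <- apply(fit$centroids, 1, classify_trend, epsilon = epsilon)
  data.frame(module = seq_len(nrow(fit$centroids)),
             primary = vapply(labs, `[[`, character(1), "primary"),
             flags = vapply(labs, function(l) paste(l$flags, collapse = ","),
                            character(1)),
             stringsAsFactors = FALSE)
}
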