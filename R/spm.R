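#' Design matrix for node-wise linear models
#'
#' Builds the fixed design shared by every node: intercept, indicator
#' columns for each non-reference group, and covariate columns (e.g. body
#' weight, femur scale, shape-mode scores, impact force). The contrast
#' selects one group indicator (group vs control difference adjusted for
#' the covariates).
#'
#' @param group factor (or character) of group labels per subject.
#' @param contrast_group the group contrasted against the reference.
#' @param covariates optional data.frame / named list of numeric
#'   covariates, one value per subject.
#' @param control reference level (default: first factor level).
#' @return object of class `SpmDesign`: list with `X`, `contrast`,
#'   `group`, `control`, `contrast_group`, `nuisance` (column indices of
#'   everything except the contrast column).
#' @export
spm_design <- function(group, contrast_group, covariates = NULL,
                       control = NULL) {
  group <- as.factor(group)
  if (is.null(control)) control <- levels(group)[1]
  if (!control %in% levels(group)) stop("control level not found")
  if (!contrast_group %in% levels(group)) stop("contrast group not found")
  if (contrast_group == control) stop("contrast group equals control")
  group <- stats::relevel(group, control)
  X <- stats::model.matrix(~group)
  colnames(X) <- sub("^group", "g_", colnames(X))
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    if (nrow(cv) != length(group)) stop("covariate rows must match subjects")
    for (nm in names(cv)) X <- cbind(X, stats::setNames(cv[[nm]], NULL))
    colnames(X)[(ncol(X) - length(cv) + 1):ncol(X)] <- names(cv)
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design error: collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  ccol <- match(paste0("g_", contrast_group), colnames(X))
  contrast <- rep(0, ncol(X))
  contrast[ccol] <- 1
  structure(list(X = X, contrast = contrast, group = group,
                 control = control, contrast_group = contrast_group,
                 nuisance = setdiff(seq_len(ncol(X)), ccol)),
            class = "SpmDesign")
}

#' Node-wise ordinary least squares t-map
#'
#' Fits the same linear model at every node and returns the t-statistic of
#' the contrast, `t = c'beta / se(c'beta)` with residual degrees of freedom
#' `n - p`.
#'
#' @param features numeric matrix, nodes x subjects.
#' @param design an `SpmDesign` (or a list with `X` and `contrast`).
#' @return list with `t` (per node), `df`, `beta` (p x nodes), `sigma2`,
#'   `contrast_estimate` (c'beta per node).
#' @export
fit_node_models <- function(features, design) {
  X <- design$X
  cvec <- design$contrast
  Y <- t(as.matrix(features))          # subjects x nodes
  if (nrow(Y) != nrow(X)) stop("features columns must match design rows")
  if (nrow(X) <= ncol(X))
    stop("need more subjects than design columns")
  xtx_inv <- solve(crossprod(X))
  beta <- xtx_inv %*% crossprod(X, Y)  # p x nodes
  resid <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  cb <- as.numeric(crossprod(cvec, beta))
  cc <- as.numeric(t(cvec) %*% xtx_inv %*% cvec)
  tval <- cb / sqrt(pmax(sigma2 * cc, .Machine$double.xmin))
  list(t = tval, df = df, beta = beta, sigma2 = sigma2,
       contrast_estimate = cb, residuals = resid)
}

#' Analysis mask from cortical thickness
#'
#' Excludes nodes whose control-group mean thickness is below the
#' resolution threshold (default 1 mm), where thin-cortex estimates are
#' unreliable.
#'
#' @param thickness nodes x subjects matrix, or a per-node vector of
#'   control means.
#' @param threshold mm (default 1).
#' @param control optional column indices (or logical) selecting the
#'   control subjects; all columns are used when omitted.
#' @return logical per-node vector, TRUE = analysed.
#' @export
build_mask <- function(thickness, threshold = 1, control = NULL) {
  m <- if (is.matrix(thickness)) {
    if (!is.null(control)) thickness <- thickness[, control, drop = FALSE]
    rowMeans(thickness)
  } else as.numeric(thickness)
  m >= threshold
}

# undirected edge matrix of the template graph
template_edges <- function(faces) {
  a <- c(faces[, 1], faces[, 2], faces[, 3])
  b <- c(faces[, 2], faces[, 3], faces[, 1])
  e <- cbind(pmin(a, b), pmax(a, b))
  unique(e)
}

# connected components of the supra-threshold node set on the template
# graph; returns list of integer vectors (node ids)
component_clusters <- function(supra, edges) {
  idx <- which(supra)
  if (!length(idx)) return(list())
  sel <- supra[edges[, 1]] & supra[edges[, 2]]
  e <- edges[sel, , drop = FALSE]
  parent <- seq_along(idx)
  names(parent) <- idx
  pos <- integer(max(idx))
  pos[idx] <- seq_along(idx)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(e)) {
    for (k in seq_len(nrow(e))) {
      a <- find(pos[e[k, 1]]); b <- find(pos[e[k, 2]])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_along(idx), find, 1L)
  split(idx, roots)
}

#' Supra-threshold clusters of a t-map
#'
#' Nodes whose one-sided t-derived p-value falls below the cluster-forming
#' threshold (default 0.005), intersected with the analysis mask and split
#' into connected components over template mesh edges.
#'
#' @param tmap per-node t-statistics.
#' @param df residual degrees of freedom.
#' @param mask logical per-node analysis mask.
#' @param faces template face matrix (connectivity).
#' @param cluster_forming_p one-sided p threshold.
#' @param direction "greater" (t positive) or "less".
#' @return list of clusters, each an integer vector of node ids, sorted by
#'   decreasing extent; attribute `t_threshold` records the t cut.
#' @export
supra_threshold_clusters <- function(tmap, df, mask, faces,
                                     cluster_forming_p = 0.005,
                                     direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (df <= 0) stop("df must be positive")
  tcrit <- stats::qt(1 - cluster_forming_p, df)
  supra <- if (direction == "greater") tmap > tcrit else tmap < -tcrit
  supra <- supra & mask
  edges <- template_edges(faces)
  cl <- component_clusters(supra, edges)
  cl <- cl[order(-lengths(cl))]
  attr(cl, "t_threshold") <- tcrit
  cl
}

#' Cluster-level inference for supra-threshold clusters
#'
#' Assigns family-wise-error-corrected p-values to supra-threshold
#' clusters by their extent.
#'
#' `method = "permutation"` (default) compares each observed extent with
#' the null distribution of the maximum cluster extent over `n_perm`
#' Freedman-Lane permutations: the reduced (nuisance-only) model is fitted,
#' its residuals are permuted across subjects, refitted under the full
#' model, and the maximal supra-threshold extent recorded. This is exact
#' under exchangeability of errors.
#'
#' `method = "rft"` uses the random-field-theory expected-cluster-count
#' approximation: residual smoothness (FWHM) is estimated from normalized
#' residual gradients along template edges, the search area is converted to
#' resels, and the cluster p-value follows the expected-Euler-characteristic
#' formula for a t field. It is an asymptotic approximation, quoted with a
#' warning on small meshes.
#'
#' @param features nodes x subjects matrix (the field under test).
#' @param design an `SpmDesign`.
#' @param mask logical per-node mask.
#' @param faces template connectivity.
#' @param method "permutation" or "rft".
#' @param cluster_forming_p one-sided cluster-forming p (default 0.005).
#' @param cluster_alpha cluster-level significance level (default 0.05).
#' @param direction "greater" or "less".
#' @param n_perm number of permutations.
#' @param seed integer seed (mandatory for permutation).
#' @return object of class `SpmResult`: list with `t`, `df`, `mask`,
#'   `clusters` (data.frame: id, extent, p, significant), `cluster_nodes`
#'   (list of node ids), `method`, `direction`, `t_threshold`,
#'   `null_max_extent` (permutation only), `smoothness` (rft only).
#' @export
cluster_inference <- function(features, design, mask, faces,
                              method = c("permutation", "rft"),
                              cluster_forming_p = 0.005,
                              cluster_alpha = 0.05,
                              direction = c("greater", "less"),
                              n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  fit <- fit_node_models(features, design)
  cl <- supra_threshold_clusters(fit$t, fit$df, mask, faces,
                                 cluster_forming_p, direction)
  tcrit <- attr(cl, "t_threshold")
  ext <- lengths(cl)
  edges <- template_edges(faces)
  null_max <- NULL
  smoothness <- NULL
  if (method == "permutation") {
    if (is.null(seed)) stop("seed is mandatory for permutation inference")
    if (n_perm < 100) warning("n_perm < 100 gives coarse p-values")
    set.seed(seed)
    X <- design$X
    Z <- X[, design$nuisance, drop = FALSE]
    Y <- t(as.matrix(features))
    hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
    fitted_red <- hz %*% Y
    resid_red <- Y - fitted_red
    xtx_inv <- solve(crossprod(X))
    cc <- as.numeric(t(design$contrast) %*% xtx_inv %*% design$contrast)
    px <- xtx_inv %*% t(X)
    avec <- as.numeric(design$contrast %*% px)   # c' (X'X)^-1 X'
    s <- nrow(Y)
    null_max <- integer(n_perm)
    for (b in seq_len(n_perm)) {
      pm <- sample.int(s)
      Yb <- fitted_red + resid_red[pm, , drop = FALSE]
      cb <- as.numeric(avec %*% Yb)
      beta <- px %*% Yb
      rs <- Yb - X %*% beta
      sig2 <- colSums(rs^2) / fit$df
      tb <- cb / sqrt(pmax(sig2 * cc, .Machine$double.xmin))
      supra <- if (direction == "greater") tb > tcrit else tb < -tcrit
      supra <- supra & mask
      if (!any(supra)) { null_max[b] <- 0L; next }
      null_max[b] <- max(lengths(component_clusters(supra, edges)))
    }
    pval <- vapply(ext, function(k) (1 + sum(null_max >= k)) / (n_perm + 1), 0)
  } else {
    if (sum(mask) < 1000)
      warning("rft approximation is unreliable on meshes with < 1000 nodes")
    smoothness <- rft_smoothness(fit$residuals, faces,
                                 sqrt(fit$sigma2 * fit$df))
    pval <- vapply(ext, function(k)
      rft_cluster_p(k, tcrit, fit$df, sum(mask), smoothness$fwhm_nodes), 0)
  }
  structure(list(t = fit$t, df = fit$df, mask = mask,
                 clusters = data.frame(
                   id = seq_along(ext), extent = as.integer(ext), p = pval,
                   significant = pval < cluster_alpha),
                 cluster_nodes = cl, method = method, direction = direction,
                 t_threshold = tcrit, cluster_alpha = cluster_alpha,
                 null_max_extent = null_max, smoothness = smoothness),
            class = "SpmResult")
}

#' @export
print.SpmResult <- function(x, ...) {
  cat(sprintf("SpmResult (%s, %s): %d cluster(s), %d significant at %.3g\n",
              x$method, x$direction, nrow(x$clusters),
              sum(x$clusters$significant), x$cluster_alpha))
  if (nrow(x$clusters)) print(utils::head(x$clusters, 10))
  invisible(x)
}

# residual smoothness: FWHM in mean-edge units from normalized residual
# gradients along edges (local-variance estimator)
rft_smoothness <- function(resid, faces, resid_norm) {
  e <- template_edges(faces)
  en <- sweep(resid, 2, pmax(resid_norm, .Machine$double.xmin), "/")
  g2 <- colMeans((en[, e[, 1], drop = FALSE] - en[, e[, 2], drop = FALSE])^2) *
    nrow(resid)
  lambda <- mean(g2) / 2
  fwhm <- sqrt(4 * log(2) / pmax(lambda, 1e-12))
  list(fwhm_nodes = fwhm, lambda = lambda)
}

# expected-EC cluster-level p for a 2D t field (Friston et al. approximation)
rft_cluster_p <- function(extent, tcrit, df, n_nodes, fwhm) {
  resels <- n_nodes / fwhm^2
  rho2 <- (4 * log(2)) / (2 * pi)^1.5 *
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2) *
    tcrit * (1 + tcrit^2 / df)^(-(df - 1) / 2)
  em <- pmax(resels * rho2, 1e-12)          # expected cluster count
  en <- n_nodes * stats::pt(tcrit, df, lower.tail = FALSE)  # expected nodes
  beta <- em / pmax(en, 1e-12)
  pnk <- exp(-beta * extent)
  1 - exp(-em * pnk)
}

#' Percent-difference summary over significant clusters
#'
#' Per node, `100 * (mean_group - mean_control) / mean_control`; per
#' cluster, the mean over its nodes and a node-count histogram of the
#' values. Nodes with zero control mean are excluded with a warning.
#'
#' @param result an `SpmResult`.
#' @param features nodes x subjects matrix.
#' @param group logical/index selector of the loading-group subjects.
#' @param control selector of the control subjects.
#' @param significant_only summarise only significant clusters (default).
#' @param breaks histogram breaks (passed to [hist()]).
#' @return data.frame (cluster id, extent, p, mean_pct_diff) with a
#'   `node_values` attribute (list of per-node percent differences) and a
#'   `histograms` attribute (list of histogram objects).
#' @export
percent_difference_summary <- function(result, features, group, control,
                                       significant_only = TRUE,
                                       breaks = "Sturges") {
  stopifnot(inherits(result, "SpmResult"))
  keep <- if (significant_only) which(result$clusters$significant)
          else seq_len(nrow(result$clusters))
  mg <- rowMeans(features[, group, drop = FALSE])
  mc <- rowMeans(features[, control, drop = FALSE])
  pct <- ifelse(mc == 0, NA_real_, 100 * (mg - mc) / mc)
  if (any(mc == 0))
    warning(sum(mc == 0), " node(s) with zero control mean excluded")
  vals <- lapply(result$cluster_nodes[keep],
                 function(v) pct[v][!is.na(pct[v])])
  out <- result$clusters[keep, c("id", "extent", "p"), drop = FALSE]
  out$mean_pct_diff <- vapply(vals, function(v)
    if (length(v)) mean(v) else NA_real_, 0)
  attr(out, "node_values") <- vals
  attr(out, "histograms") <- lapply(vals, function(v)
    if (length(v)) graphics::hist(v, breaks = breaks, plot = FALSE) else NULL)
  out
}

#' Composite map across loading groups
#'
#' Labels every template node with the set of groups whose significant
#' clusters contain it; nodes in no significant cluster are labelled "n/s".
#'
#' @param results named list of `SpmResult`s (one per group), sharing the
#'   template.
#' @param n_nodes number of template nodes.
#' @return character vector of labels per node (group names joined by
#'   "+", or "n/s").
#' @export
composite_map <- function(results, n_nodes) {
  if (is.null(names(results)) || any(names(results) == ""))
    stop("results must be a named list (group names)")
  sizes <- vapply(results, function(r) length(r$t), 0L)
  if (any(sizes != n_nodes))
    stop("argument error: results do not share the template node count")
  hit <- matrix(FALSE, n_nodes, length(results),
                dimnames = list(NULL, names(results)))
  for (g in names(results)) {
    r <- results[[g]]
    sig <- which(r$clusters$significant)
    for (k in sig) hit[r$cluster_nodes[[k]], g] <- TRUE
  }
  apply(hit, 1, function(row)
    if (!any(row)) "n/s" else paste(names(results)[row], collapse = "+"))
}
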