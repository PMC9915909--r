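#' Column-standardize a unit-by-indicator matrix
#'
#' Each column is centred to mean 0 and scaled to sample standard
#' deviation 1 (n - 1 denominator).
#'
#' @param mat numeric matrix with at least two rows.
#' @return Standardized matrix of the same shape.
#' @export
standardize <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("standardize needs at least 2 units")
  if (any(!is.finite(mat))) stop("standardize requires finite input")
  sds <- apply(mat, 2L, stats::sd)
  zero <- which(sds == 0)
  if (length(zero)) {
    nm <- colnames(mat)[zero[1L]]
    stop("indicator '", if (is.null(nm)) zero[1L] else nm,
         "' has zero variance")
  }
  scale(mat, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Correlation-matrix principal component analysis
#'
#' Eigendecomposition of the indicator correlation matrix, components
#' ordered by descending eigenvalue.  Each component's loading vector is
#' sign-oriented so that its largest-magnitude loading is positive (the
#' composite score of [composite_score()] is sign-sensitive, so the
#' convention is fixed rather than left to the eigensolver).  Both raw
#' eigenvector loadings and eigenvector-times-sqrt(eigenvalue) scaled
#' loadings (indicator-component correlations) are reported.
#'
#' @param mat standardized unit-by-indicator matrix (see [standardize()]).
#' @param threshold cumulative variance-contribution cut-off in percent
#'   used by [select_components()]; default 80.
#' @return An object of class `cei_pca` with elements `loadings` (rows =
#'   components, columns = indicators), `scaled_loadings`, `eigenvalues`,
#'   `contribution` (percent), `cumulative` (percent), `n_selected`, and
#'   `scores` (units x components).
#' @export
cei_pca <- function(mat, threshold = 80) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("pca requires finite input")
  R <- stats::cor(mat)
  eig <- eigen(R, symmetric = TRUE)
  lam <- eig$values
  V <- eig$vectors                       # columns = components
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  loadings <- t(V)
  colnames(loadings) <- colnames(mat)
  rownames(loadings) <- paste0("PC", seq_len(nrow(loadings)))
  contribution <- 100 * lam / sum(lam)
  cumulative <- cumsum(contribution)
  scores <- mat %*% t(loadings)
  colnames(scores) <- rownames(loadings)
  structure(list(loadings = loadings,
                 scaled_loadings = loadings * sqrt(pmax(lam, 0)),
                 eigenvalues = lam,
                 contribution = contribution,
                 cumulative = cumulative,
                 n_selected = select_components(contribution, threshold),
                 scores = scores),
            class = "cei_pca")
}

#' @export
print.cei_pca <- function(x, ...) {
  cat("correlation-matrix PCA:", ncol(x$loadings), "indicators,",
      x$n_selected, "component(s) selected\n")
  tab <- rbind(eigenvalue = x$eigenvalues,
               `contribution %` = x$contribution,
               `cumulative %` = x$cumulative)
  colnames(tab) <- rownames(x$loadings)
  print(round(tab, 3))
  invisible(x)
}

#' Number of components reaching a cumulative contribution threshold
#'
#' Returns the smallest n whose cumulative variance-contribution rate
#' reaches the threshold; if it is never reached, all components are
#' retained.
#'
#' @param contribution variance-contribution rates in percent, descending.
#' @param threshold cumulative percent cut-off (default 80).
#' @return Integer count of retained components.
#' @export
select_components <- function(contribution, threshold = 80) {
  if (length(contribution) == 0L) stop("empty contribution list")
  if (any(diff(contribution) > 1e-9))
    stop("contribution rates must be descending")
  if (sum(contribution) > 100 + 1e-6)
    stop("contribution rates sum to more than 100%")
  cum <- cumsum(contribution)
  hit <- which(cum >= threshold)
  if (length(hit)) hit[1L] else length(contribution)
}

#' Variance-contribution-weighted composite score
#'
#' The comprehensive index P is the weighted sum of the retained
#' component scores, each weighted by its variance-contribution rate
#' taken as a fraction: P = sum_{i<=n} (k_i / 100) * X_i.
#'
#' @param pca a [cei_pca()] result.
#' @param n number of components to retain; defaults to the PCA's
#'   80%-rule selection.
#' @return List with `P` (per-unit score), `weights_used` (fractions) and
#'   `n_components`.
#' @export
composite_score <- function(pca, n = pca$n_selected) {
  stopifnot(inherits(pca, "cei_pca"))
  n <- as.integer(n)
  if (n < 1L || n > length(pca$eigenvalues))
    stop("invalid number of retained components: ", n)
  w <- pca$contribution[seq_len(n)] / 100
  P <- drop(pca$scores[, seq_len(n), drop = FALSE] %*% w)
  list(P = P, weights_used = w, n_components = n)
}

#' Build the comprehensive ecological index from indicator panels
#'
#' For every timepoint the regions-by-indicators matrix is standardized,
#' decomposed by correlation-matrix PCA, and collapsed to the composite
#' score; the per-year PCA reports are returned alongside the CEI panel.
#'
#' @param panels named list of indicator [panel_table()]s sharing regions
#'   and timepoints.
#' @param indicator_order indicator order for the PCA matrix columns.
#' @param threshold cumulative-contribution cut-off in percent.
#' @return List with `panel` (the CEI [panel_table()]) and `pca` (one
#'   [cei_pca()] per timepoint, named by year).
#' @export
build_cei <- function(panels,
                      indicator_order = c("NDVI", "LAI", "GPP", "LST", "Wet"),
                      threshold = 80) {
  if (is.null(names(panels)) || !all(indicator_order %in% names(panels)))
    stop("panels must be a named list containing: ",
         paste(indicator_order, collapse = ", "))
  ref <- panels[[indicator_order[1L]]]
  for (nm in indicator_order) {
    p <- panels[[nm]]
    if (!identical(p$region_ids, ref$region_ids) ||
        !identical(p$years, ref$years))
      stop("panel '", nm, "' does not share regions/timepoints")
    if (any(p$missing))
      stop("panel '", nm, "' has missing cells; interpolate first")
  }
  n_t <- length(ref$years)
  cei_vals <- matrix(NA_real_, length(ref$region_ids), n_t)
  pca_by_year <- vector("list", n_t)
  names(pca_by_year) <- as.character(ref$years)
  for (t in seq_len(n_t)) {
    m <- vapply(indicator_order, function(nm) panels[[nm]]$values[, t],
                numeric(length(ref$region_ids)))
    z <- standardize(m)
    fit <- cei_pca(z, threshold = threshold)
    cei_vals[, t] <- composite_score(fit)$P
    pca_by_year[[t]] <- fit
  }
  list(panel = panel_table(cei_vals, ref$region_ids, ref$years, "CEI"),
       pca = pca_by_year)
}
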