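#' Partition metric variance into species and individual components
#'
#' Nested sums-of-squares decomposition of each metric: species, individual
#' within species, residual. The percentage of total SS attributable to each
#' level quantifies whether a metric is a species-level trait or an
#' individual one. The species effect is F-tested against the
#' individual-within-species mean square (the correct denominator when
#' individuals are the replicates); with one observation per individual the
#' individual level is the residual.
#'
#' @param data Metric table (e.g. from [fit_step_distributions()],
#'   [daily_path_metrics()] or [lifephase_metrics()]).
#' @param metrics Character vector of metric column names; default all
#'   numeric columns except identifiers.
#' @param species,individual Names of the factor columns.
#' @return Tibble with one row per metric: `metric`, `pct_species`,
#'   `pct_individual`, `statistic` (F), `df1`, `df2`, `p_value`, `n`.
#' @export
variance_partition <- function(data, metrics = NULL, species = "species",
                               individual = "individual_id") {
  if (length(unique(data[[species]])) < 2) {
    abort("Variance partition needs >= 2 species.",
          class = "msms_config_error")
  }
  if (is.null(metrics)) {
    metrics <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                       c(species, individual, "n_fixes", "n_steps",
                         "n_turns", "period_date"))
  }
  purrr::map_dfr(metrics, function(m) {
    d <- data[!is.na(data[[m]]), c(species, individual, m)]
    names(d) <- c("species", "individual", "y")
    d$species <- factor(d$species)
    d$individual <- factor(d$individual)
    ss_tot <- sum((d$y - mean(d$y))^2)
    if (ss_tot == 0) {
      abort(sprintf("Metric '%s' has zero variance.", m),
            class = "msms_degenerate_data")
    }
    # sequential (type I) SS from nested model deviances: species, then
    # individual-within-species (ids are unique across species, so the plain
    # individual term is the nested one), then residual
    replicated <- any(table(d$individual) > 1)
    fit_sp <- lm(y ~ species, data = d)
    ss_sp <- ss_tot - stats::deviance(fit_sp)
    df_sp <- nlevels(d$species) - 1
    if (replicated) {
      fit_in <- lm(y ~ species + individual, data = d)
      ss_in <- stats::deviance(fit_sp) - stats::deviance(fit_in)
      df_in <- nlevels(d$individual) - nlevels(d$species)
    } else {
      ss_in <- stats::deviance(fit_sp)
      df_in <- nrow(d) - nlevels(d$species)
    }
    f <- (ss_sp / df_sp) / (ss_in / df_in)
    p <- pf(f, df_sp, df_in, lower.tail = FALSE)
    tibble::tibble(metric = m,
                   pct_species = 100 * ss_sp / ss_tot,
                   pct_individual = 100 * ss_in / ss_tot,
                   statistic = f, df1 = df_sp, df2 = df_in, p_value = p,
                   n = nrow(d))
  })
}

#' Principal component syndrome space
#'
#' Standardized (correlation-matrix) PCA of a metric table. Metrics listed
#' in `log_metrics` are log-transformed first (the straightness index is by
#' convention, since it is bounded and right-skewed toward 1). Rows with any
#' missing metric are dropped (count reported). Components with eigenvalue
#' greater than 1 are retained (Kaiser rule), and each component's sign is
#' fixed so its largest-loading metric loads positive, making scores
#' reproducible.
#'
#' @param data Metric table.
#' @param metrics Metric columns; default all numeric non-identifier
#'   columns.
#' @param log_metrics Metrics to log-transform (values must be positive;
#'   non-positive rows are dropped with the incomplete ones).
#' @param species,individual Factor columns carried into the scores.
#' @return Object of class `syndrome_space`: `loadings` (metrics x
#'   components), `scores` (tibble with factor columns and PC scores),
#'   `eigenvalues`, `retained`, `pct_variance`, `cum_pct_retained`,
#'   `metrics`, `n_dropped`.
#' @export
pca_syndromes <- function(data, metrics = NULL, log_metrics = "straightness",
                          species = "species", individual = "individual_id") {
  if (is.null(metrics)) {
    metrics <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                       c(species, individual, "n_fixes", "n_steps",
                         "n_turns", "period_date"))
  }
  d <- data
  for (m in intersect(log_metrics, metrics)) {
    d[[m]] <- ifelse(d[[m]] > 0, log(d[[m]]), NA_real_)
  }
  X <- as.data.frame(d[, metrics, drop = FALSE])
  keep <- complete.cases(X)
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 3) abort("PCA needs >= 3 complete rows.",
                         class = "msms_insufficient_data")
  vars <- vapply(X, var, 0)
  if (any(vars == 0)) {
    warn(sprintf("Dropping zero-variance metric(s): %s",
                 paste(names(vars)[vars == 0], collapse = ", ")))
    metrics <- metrics[vars > 0]
    X <- X[, vars > 0, drop = FALSE]
  }
  if (ncol(X) < 2) abort("PCA needs >= 2 non-constant metrics.",
                         class = "msms_insufficient_data")
  Z <- scale(as.matrix(X))
  R <- cor(as.matrix(X))
  eig <- eigen(R, symmetric = TRUE)
  L <- eig$vectors
  # deterministic sign: largest-|loading| metric of each component positive
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(X), paste0("PC", seq_len(ncol(L))))
  scores <- Z %*% L
  retained <- which(eig$values > 1)
  pct <- 100 * eig$values / sum(eig$values)
  meta <- d[keep, intersect(c(individual, species, "period_date"), names(d)),
            drop = FALSE]
  structure(list(
    loadings = L,
    scores = dplyr::bind_cols(tibble::as_tibble(meta),
                              tibble::as_tibble(scores)),
    eigenvalues = eig$values,
    retained = retained,
    pct_variance = pct,
    cum_pct_retained = sum(pct[retained]),
    metrics = colnames(X),
    n_dropped = n_dropped), class = "syndrome_space")
}

#' @export
print.syndrome_space <- function(x, ...) {
  cat(sprintf("Syndrome space: %d metrics, %d rows; %d component(s) with eigenvalue > 1 explaining %.1f%% of variance\n",
              length(x$metrics), nrow(x$scores), length(x$retained),
              x$cum_pct_retained))
  invisible(x)
}

#' @export
tidy.syndrome_space <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "metric") %>%
    tidyr::pivot_longer(-"metric", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.syndrome_space <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores), n_metrics = length(x$metrics),
                 n_retained = length(x$retained),
                 cum_pct_retained = x$cum_pct_retained,
                 n_dropped = x$n_dropped)
}

#' Cluster individuals in syndrome space
#'
#' Ward agglomerative clustering of the rows of a syndrome space on its
#' retained principal component scores, with the mean silhouette width as a
#' separation diagnostic.
#'
#' @param space A [pca_syndromes()] object.
#' @param k Number of clusters (2 to n-1).
#' @return Object of class `syndrome_clusters`: `assignments` (the score
#'   tibble plus `cluster`), `k`, `mean_silhouette`.
#' @export
cluster_individuals <- function(space, k) {
  S <- as.matrix(space$scores[, paste0("PC", space$retained), drop = FALSE])
  n <- nrow(S)
  if (k < 2 || k > n - 1) {
    abort(sprintf("k must be in [2, %d].", n - 1), class = "msms_config_error")
  }
  hc <- hclust(dist(S), method = "ward.D2")
  cl <- cutree(hc, k = k)
  sil <- cluster::silhouette(cl, dist(S))
  out <- space$scores
  out$cluster <- cl
  structure(list(assignments = out, k = k,
                 mean_silhouette = mean(sil[, "sil_width"])),
            class = "syndrome_clusters")
}

#' @export
print.syndrome_clusters <- function(x, ...) {
  cat(sprintf("Syndrome clustering: k = %d, mean silhouette %.3f\n",
              x$k, x$mean_silhouette))
  invisible(x)
}

#' @export
tidy.syndrome_clusters <- function(x, ...) x$assignments

#' @export
glance.syndrome_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, mean_silhouette = x$mean_silhouette,
                 n = nrow(x$assignments))
}
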