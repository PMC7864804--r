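## Meta-analysis of metric behavior: score tables, correlation matrices,
## metric clustering by 1-|r| similarity, percentile summaries, and
## composite Z-score rankings.

#' Default metric orientation registry
#'
#' Whether a larger score means a better model. Rankings refuse metrics
#' with no declared orientation: a silent sign error is the worst
#' failure mode of composite ranking.
#'
#' @return named character vector, `"higher"` or `"lower"`
#' @export
default_orientations <- function() {
  c(ccbox = "higher", ccmask = "higher", ccpeaks = "higher", ccc = "higher",
    ccc_ov = "higher", lap = "higher", mi = "higher", mi_ov = "higher",
    smoc = "higher", fsc05 = "lower", fscavg = "higher",
    atom_inclusion = "higher", env = "higher", qscore = "higher",
    emringer = "higher",
    bond_rmsd = "lower", angle_rmsd = "lower", clashscore = "lower",
    rama_outliers = "lower", rotamer_outliers = "lower",
    cablam_outliers = "lower", calpha_outliers = "lower",
    gdt_ts = "higher", gdc_all = "higher", gdc_sc = "higher",
    ca_rmsd = "lower", lddt = "higher", cad = "higher",
    hbpr_gt6 = "higher", davis_qa = "higher")
}

#' The bundled composite-Z weight sets
#'
#' The three default weight combinations used for group ranking: a
#' coordinates-only set (CaBLAM outliers 0.5, CA-geometry outliers 0.3,
#' clashscore 0.2), a fit-to-map set (EMRinger 0.3, Q-score 0.3, atom
#' inclusion 0.2, SMOC 0.2) and a versus-reference set (LDDT 0.9,
#' GDC-all 0.9, HBPR>6 0.2).
#'
#' @return named list of named weight vectors
#' @export
default_weight_sets <- function() {
  list(
    coords_only = c(cablam_outliers = 0.5, calpha_outliers = 0.3,
                    clashscore = 0.2),
    fit_to_map = c(emringer = 0.3, qscore = 0.3, atom_inclusion = 0.2,
                   smoc = 0.2),
    vs_reference = c(lddt = 0.9, gdc_all = 0.9, hbpr_gt6 = 0.2))
}

#' Load a model-scores table from CSV
#'
#' Expects a header with `model` and `target` identifier columns
#' (additional identifier columns `team`, `category` are carried along);
#' every other column is treated as a metric. Unparsable cells become
#' missing values and are counted; duplicated (model, target) rows are
#' an error.
#'
#' @param path CSV file
#' @param orientations named orientation vector (see
#'   [default_orientations()])
#' @return object of class `em_scoretable`
#' @export
load_scores <- function(path, orientations = default_orientations()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  score_table(df, orientations)
}

#' @rdname load_scores
#' @param df data.frame with `model`, `target` and metric columns
#' @export
score_table <- function(df, orientations = default_orientations()) {
  if (!all(c("model", "target") %in% names(df)))
    stop_emvalid("score table needs 'model' and 'target' columns")
  key <- paste(df$model, df$target)
  if (anyDuplicated(key))
    stop_emvalid("duplicate (model, target) row: %s", key[duplicated(key)][1])
  id_cols <- intersect(c("model", "target", "team", "category"), names(df))
  metric_cols <- setdiff(names(df), id_cols)
  for (m in metric_cols) {
    v <- df[[m]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    df[[m]] <- v
  }
  n_missing <- sum(is.na(df[metric_cols]))
  structure(list(data = df, metrics = metric_cols, id_cols = id_cols,
                 orientations = orientations, n_missing = n_missing),
            class = "em_scoretable")
}

#' @export
print.em_scoretable <- function(x, ...) {
  cat(sprintf("em_scoretable: %d rows, %d metrics (%d missing cells), targets: %s\n",
              nrow(x$data), length(x$metrics), x$n_missing,
              paste(unique(x$data$target), collapse = ", ")))
  invisible(x)
}

#' Pairwise Pearson correlation matrix of metrics
#'
#' `scope = "pooled"`: one correlation over all rows.
#' `scope = "per_target"`: a list of per-target matrices.
#' `scope = "per_target_averaged"`: the element-wise mean of the
#' per-target matrices. Pairwise-complete observations throughout;
#' zero-variance metrics give `NA` entries, flagged in the `undefined`
#' attribute and excluded from clustering with a warning.
#'
#' @param table an `em_scoretable`
#' @param scope correlation scope
#' @return a `em_corrmatrix` (matrix with attributes) or list thereof
#' @export
correlation_matrix <- function(table,
                               scope = c("pooled", "per_target",
                                         "per_target_averaged")) {
  scope <- match.arg(scope)
  mat <- function(df) {
    m <- as.matrix(df[table$metrics])
    if (nrow(m) < 3) stop_emvalid("need >= 3 rows per correlation sample")
    suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs"))
    diag(r) <- 1
    structure(r, undefined = table$metrics[colSums(is.na(r)) >= ncol(r) - 1],
              class = c("em_corrmatrix", class(r)))
  }
  if (scope == "pooled") return(mat(table$data))
  split_df <- split(table$data, table$data$target)
  mats <- lapply(split_df, mat)
  if (scope == "per_target") return(mats)
  num <- Reduce(`+`, lapply(mats, function(m) { m[is.na(m)] <- 0; m }))
  den <- Reduce(`+`, lapply(mats, function(m) 1 * !is.na(m)))
  avg <- num / den
  diag(avg) <- 1
  structure(avg, undefined = character(),
            class = c("em_corrmatrix", class(avg)))
}

#' Cluster metrics by correlation similarity
#'
#' Complete-linkage agglomerative clustering on the distance `1 - |r|`
#' (so perfectly anti-correlated metrics are as close as perfectly
#' correlated ones), cut at `n_clusters`. Metric order is made
#' lexicographic first so tie-breaking is deterministic. The number of
#' clusters is a required argument; merge heights are returned so the
#' cut can be inspected.
#'
#' @param corr an `em_corrmatrix`
#' @param n_clusters integer in [1, n_metrics]
#' @return list of class `em_clusters`: `labels` (named integer vector),
#'   `merge_heights`, and the `hclust` object
#' @export
cluster_metrics <- function(corr, n_clusters) {
  undef <- attr(corr, "undefined")
  if (length(undef)) {
    warning("excluding undefined metrics from clustering: ",
            paste(undef, collapse = ", "))
    keep <- setdiff(colnames(corr), undef)
    corr <- corr[keep, keep]
  }
  if (any(is.na(corr))) stop_emvalid("correlation matrix has undefined entries")
  ord <- order(colnames(corr))
  corr <- corr[ord, ord]
  n <- ncol(corr)
  if (n_clusters < 1 || n_clusters > n)
    stop_emvalid("n_clusters must be in [1, %d]", n)
  d <- stats::as.dist(1 - abs(corr))
  hc <- stats::hclust(d, method = "complete")
  labels <- stats::cutree(hc, k = n_clusters)
  structure(list(labels = labels, merge_heights = hc$height, hclust = hc),
            class = "em_clusters")
}

#' @export
print.em_clusters <- function(x, ...) {
  k <- max(x$labels)
  for (i in seq_len(k))
    cat(sprintf("cluster %d: %s\n", i,
                paste(names(x$labels)[x$labels == i], collapse = ", ")))
  invisible(x)
}

#' Composite Z-score ranking
#'
#' Standardizes every metric within each target over that target's
#' models (mean 0, sd 1), negates lower-is-better metrics, and combines
#' them with the given weights into a composite Z per (model, target).
#' Metrics with zero variance within a target are dropped for that
#' target (logged in the result); missing scores simply drop out of the
#' weighted sum. Group scores are means of model composites; subsets of
#' targets (e.g. a high/low resolution split) can be averaged via
#' `target_subset`.
#'
#' @param table an `em_scoretable`
#' @param weights named weight vector over metrics
#' @param target_subset optional character vector of targets to include
#' @return object of class `em_zranking`: `z` (per model/target/metric),
#'   `composite` (per model/target), `by_model` averages, `dropped` log
#' @export
composite_z <- function(table, weights, target_subset = NULL) {
  df <- table$data
  if (!is.null(target_subset)) df <- df[df$target %in% target_subset, ]
  mets <- names(weights)
  missing_m <- setdiff(mets, table$metrics)
  if (length(missing_m))
    stop_emvalid("weighted metrics absent from table: %s",
                 paste(missing_m, collapse = ", "))
  orient <- table$orientations[mets]
  if (anyNA(orient))
    stop_emvalid("no declared orientation for: %s",
                 paste(mets[is.na(orient)], collapse = ", "))
  zs <- list(); dropped <- list()
  for (tg in unique(df$target)) {
    sub <- df[df$target == tg, ]
    for (m in mets) {
      v <- sub[[m]]
      mu <- mean(v, na.rm = TRUE); sdv <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(sdv) || sdv == 0) {
        dropped[[length(dropped) + 1]] <- data.frame(target = tg, metric = m)
        next
      }
      z <- (v - mu) / sdv
      if (orient[m] == "lower") z <- -z
      zs[[length(zs) + 1]] <- data.frame(
        model = sub$model, target = tg, metric = m, z = z,
        weight = unname(weights[m]), stringsAsFactors = FALSE)
    }
  }
  if (!length(zs)) stop_emvalid("no metric had variance in any target")
  zl <- do.call(rbind, zs)
  zl <- zl[!is.na(zl$z), ]
  comp <- stats::aggregate(cbind(wz = zl$z * zl$weight) ~ model + target,
                           data = zl, FUN = sum)
  names(comp)[3] <- "composite"
  by_model <- stats::aggregate(composite ~ model, data = comp, FUN = mean)
  structure(list(z = zl, composite = comp, by_model = by_model,
                 dropped = if (length(dropped)) do.call(rbind, dropped) else
                   data.frame(target = character(), metric = character())),
            class = "em_zranking")
}

#' @export
print.em_zranking <- function(x, ...) {
  b <- x$by_model[order(-x$by_model$composite), ]
  cat("composite Z by model:\n")
  for (i in seq_len(min(10, nrow(b))))
    cat(sprintf("  %-12s %+.3f\n", b$model[i], b$composite[i]))
  invisible(x)
}

#' Percentile summary of a metric by target
#'
#' 10th/25th/50th/75th/90th percentiles per target using the
#' linear-interpolation convention (`stats::quantile` type 7), plus the
#' raw points and a degenerate-box flag when the quartile limits
#' coincide.
#'
#' @param table an `em_scoretable`
#' @param metric metric column name
#' @return data.frame, one row per target, with attribute `points`
#' @export
distribution_summary <- function(table, metric) {
  if (!metric %in% table$metrics) stop_emvalid("unknown metric: %s", metric)
  df <- table$data
  rows <- lapply(split(df, df$target), function(sub) {
    v <- sub[[metric]][!is.na(sub[[metric]])]
    if (!length(v)) return(NULL)
    q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7,
                         names = FALSE)
    data.frame(target = sub$target[1], n = length(v),
               p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
               degenerate_box = q[2] == q[4], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "points") <- split(df[[metric]], df$target)
  out
}
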