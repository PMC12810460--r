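# Statistical analysis harness: solved/unsolved clustering, efficiency with
# propagated uncertainty, seed-quality class labelling, random-forest
# classification and the resolution cut-off benchmark.

#' Assemble a trial record
#'
#' One phasing attempt's structure features, seed metrics and final metrics,
#' in the shape consumed by the evaluation harness.
#'
#' @param structure The ground-truth [crystal_structure()].
#' @param rs The `reflection_set` that was phased.
#' @param seed The `phase_seed` used.
#' @param solution The resulting `phase_solution`.
#' @param structure_id Identifier for the structure.
#' @return One-row data.frame with Table-style feature columns
#'   (`N_asym, maxCellSize, minCellSize, Perc, Compl, maxW, Pseudo, N_refl,
#'   RES, REFLEC_seed, RES_seed, Vol`), seed metrics (`MPE_seed, CORR_seed`)
#'   and final metrics (`MPE_final, CORR_final, R_f`).
#' @export
trial_record <- function(structure, rs, seed, solution, structure_id = NA) {
  f <- structure$features
  sm <- evaluate_seed(seed, rs)
  srows <- seed_rows(seed, rs)
  data.frame(
    structure_id = structure_id,
    N_asym = f$N_asym,
    maxCellSize = f$maxCellSize,
    minCellSize = f$minCellSize,
    Perc = 100 * length(srows) / nrow(rs$refl),
    Compl = 100 * (rs$completeness %||% 1),
    maxW = f$maxW,
    Pseudo = f$Pseudo,
    N_refl = nrow(rs$refl),
    RES = rs$res_limit,
    REFLEC_seed = length(srows),
    RES_seed = min(rs$refl$d[srows]),
    Vol = f$Vol,
    MPE_seed = sm$MPE_seed,
    CORR_seed = sm$CORR_seed,
    MPE_final = solution$MPE_final,
    CORR_final = solution$CORR_final,
    R_f = solution$R_f,
    provider = seed$provenance,
    path = solution$path,
    stringsAsFactors = FALSE
  )
}

#' Two-means solved/unsolved clustering
#'
#' Standardizes the final metrics (`MPE_final`, `CORR_final`, `R_f` by
#' default), clusters with 2-means (Hartigan-Wong), labels the cluster whose
#' centroid has the lower `MPE_final` as solved, and computes silhouette
#' widths.
#'
#' @param records data.frame of trial records.
#' @param metric_cols Columns to cluster on.
#' @param rng_seed Seed for the k-means starts.
#' @param nstart Random starts for [stats::kmeans()].
#' @return List with `solved` (logical per record), `silhouette` (widths),
#'   `mean_silhouette`, `centers` (on the original scale), `degenerate`.
#' @export
cluster_solved <- function(records, metric_cols = c("MPE_final", "CORR_final", "R_f"),
                           rng_seed = 1, nstart = 10) {
  x <- as.matrix(records[, metric_cols])
  if (nrow(x) < 2L || !all(is.finite(x))) stopf("cluster_solved: need >= 2 records with finite metrics")
  sdv <- apply(x, 2L, stats::sd)
  if (all(sdv == 0)) {
    return(list(solved = rep(TRUE, nrow(x)), silhouette = rep(0, nrow(x)),
                mean_silhouette = 0, centers = rbind(colMeans(x)),
                degenerate = TRUE))
  }
  xs <- scale(x[, sdv > 0, drop = FALSE])
  km <- with_rng(rng_seed, stats::kmeans(xs, centers = 2, nstart = nstart))
  mpe_by_cluster <- tapply(records$MPE_final, km$cluster, mean)
  solved_cluster <- as.integer(names(which.min(mpe_by_cluster)))
  sil <- cluster::silhouette(km$cluster, stats::dist(xs))
  list(solved = unname(km$cluster == solved_cluster),
       silhouette = sil[, "sil_width"],
       mean_silhouette = mean(sil[, "sil_width"]),
       centers = rowsum(x, km$cluster) / as.vector(table(km$cluster)),
       degenerate = FALSE)
}

#' Phasing efficiency with propagated uncertainty
#'
#' `E = 100 D / N` percent, with `sigma_E = sqrt(E (100 - E) / N)`.
#'
#' @param d Number of correctly classified (solved) structures.
#' @param n Total number of structures (`> 0`).
#' @return List with `E`, `D`, `N`, `sigma_E`.
#' @examples
#' efficiency(13, 15)$E  # 86.7
#' @export
efficiency <- function(d, n) {
  if (n <= 0) stopf("efficiency: N must be positive")
  e <- 100 * d / n
  list(E = e, D = d, N = n, sigma_E = sqrt(e * (100 - e) / n))
}

#' Seed-quality class thresholds and labels
#'
#' Computes `Q1` of `MPE_seed` and `Q3` of `CORR_seed` over the unsolved
#' records (linear-interpolation quantiles, type 7) and labels every record:
#' Class 1 when `MPE_seed <= Q1` and `CORR_seed >= Q3` (boundaries
#' inclusive), Class 0 otherwise. The reliable-seed "green" sublabel uses the
#' fixed thresholds `MPE_seed < 25` degrees and `CORR_seed > 0.8`.
#'
#' @param records data.frame with `MPE_seed`, `CORR_seed`.
#' @param solved Logical vector (from [cluster_solved()]).
#' @return List with `Q1`, `Q3`, `class1` (logical), `green` (logical).
#' @export
class_thresholds <- function(records, solved) {
  uns <- records[!solved, , drop = FALSE]
  if (nrow(uns) < 4L) stopf("class_thresholds: need at least 4 unsolved records")
  q1 <- as.numeric(stats::quantile(uns$MPE_seed, 0.25, type = 7))
  q3 <- as.numeric(stats::quantile(uns$CORR_seed, 0.75, type = 7))
  list(Q1 = q1, Q3 = q3,
       class1 = records$MPE_seed <= q1 & records$CORR_seed >= q3,
       green = records$MPE_seed < 25 & records$CORR_seed > 0.8)
}

# stratified k-fold assignment (balanced within each class)
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Random-forest seed-quality classification
#'
#' Fits a random forest (500 trees, `sqrt(p)` features per split) to predict
#' the Class 1/0 label from the structure features, with stratified tenfold
#' cross-validation. Out-of-fold probabilities are pooled into a single ROC
#' curve; the operating threshold is the one with the highest sensitivity
#' among those with specificity of at least 80% (ties resolved toward higher
#' specificity). Gini importances come from a forest refitted on all records.
#'
#' @param records data.frame of trial records.
#' @param labels Logical or 0/1 vector (Class 1 indicator).
#' @param features Feature columns to use.
#' @param rng_seed Integer seed (folds and forests are reproducible).
#' @param ntree Number of trees.
#' @param k Number of CV folds.
#' @param min_specificity Specificity floor for threshold selection.
#' @return List with `prob` (pooled out-of-fold Class 1 probabilities), `roc`
#'   (a [pROC::roc] object), `auc`, `threshold`, `confusion` (predicted x
#'   actual), `importance` (mean decrease Gini, descending), `sensitivity`,
#'   `specificity` at the chosen threshold.
#' @export
rf_classify <- function(records, labels,
                        features = c("N_asym", "maxCellSize", "minCellSize",
                                     "Perc", "Compl", "maxW", "Pseudo",
                                     "N_refl", "RES", "REFLEC_seed",
                                     "RES_seed", "Vol"),
                        rng_seed = 1, ntree = 500, k = 10,
                        min_specificity = 0.80) {
  y <- factor(as.integer(labels), levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2L) stopf("rf_classify: both classes must be present")
  features <- intersect(features, names(records))
  x <- records[, features, drop = FALSE]
  k <- min(k, min(table(y)))
  with_rng(rng_seed, {
    fold <- stratified_folds(as.integer(y), k)
    prob <- numeric(nrow(x))
    for (f in seq_len(k)) {
      te <- fold == f
      fit <- randomForest::randomForest(x[!te, , drop = FALSE], y[!te],
                                        ntree = ntree)
      prob[te] <- stats::predict(fit, x[te, , drop = FALSE], type = "prob")[, "1"]
    }
    roc <- pROC::roc(response = y, predictor = prob, levels = c("0", "1"),
                     direction = "<", quiet = TRUE)
    co <- pROC::coords(roc, x = "all", ret = c("threshold", "sensitivity",
                                               "specificity"), transpose = FALSE)
    ok <- co$specificity >= min_specificity
    if (!any(ok)) ok <- co$specificity == max(co$specificity)
    cand <- co[ok, , drop = FALSE]
    cand <- cand[order(-cand$sensitivity, -cand$specificity), , drop = FALSE]
    thr <- cand$threshold[1L]
    pred <- factor(as.integer(prob >= thr), levels = c(0, 1))
    confusion <- table(predicted = pred, actual = y)
    fit_all <- randomForest::randomForest(x, y, ntree = ntree, importance = FALSE)
    imp <- sort(fit_all$importance[, "MeanDecreaseGini"], decreasing = TRUE)
    list(prob = prob, roc = roc, auc = as.numeric(pROC::auc(roc)),
         threshold = thr, confusion = confusion, importance = imp,
         sensitivity = cand$sensitivity[1L], specificity = cand$specificity[1L])
  })
}

#' Per-bin distributions of CORR_seed across a feature
#'
#' Bins are left-open/right-closed (`(a, b]`), with open outer intervals.
#'
#' @param records data.frame of trial records.
#' @param feature Feature column to stratify on.
#' @param bin_edges Interior bin edges (e.g. `c(50, 100)` for
#'   `<=50, 50-100, >100`).
#' @param value Column whose distribution is reported.
#' @return data.frame with `bin`, `n`, `median`; empty bins are flagged with
#'   a warning.
#' @export
stratified_distributions <- function(records, feature, bin_edges,
                                     value = "CORR_seed") {
  x <- records[[feature]]
  if (is.null(x)) stopf("stratified_distributions: no feature '%s'", feature)
  breaks <- c(-Inf, sort(unique(bin_edges)), Inf)
  bin <- cut(x, breaks = breaks, right = TRUE)
  med <- tapply(records[[value]], bin, stats::median)
  n <- as.vector(table(bin))
  if (any(n == 0)) warnf("stratified_distributions: empty bin(s) %s",
                         paste(levels(bin)[n == 0], collapse = ", "))
  data.frame(bin = levels(bin), n = n, median = as.numeric(med),
             row.names = NULL)
}

#' Run a cohort of phasing trials
#'
#' Builds a reflection set for each structure, applies the requested seed
#' provider and strategy, and collects trial records.
#'
#' @param structures List of [crystal_structure()] objects.
#' @param providers Character vector of seed providers (`"true"`, `"noisy"`,
#'   `"random"`).
#' @param strategy Phasing strategy for [solve_structure()].
#' @param res_limit Base resolution limit in angstroms.
#' @param cutoff Optional resolution cut-off applied before phasing (`NA` for
#'   none).
#' @param flip_fraction Noisy-provider flip fraction.
#' @param rng_seed Integer seed; per-trial seeds are derived from it.
#' @param ... Passed to [solve_structure()].
#' @return data.frame of trial records (one row per structure x provider).
#' @export
run_cohort <- function(structures, providers = c("true", "noisy", "random"),
                       strategy = "seed", res_limit = 0.9, cutoff = NA,
                       flip_fraction = 0.1, rng_seed = 1, ...) {
  out <- list()
  for (si in seq_along(structures)) {
    st <- structures[[si]]
    rs <- make_reflections(st, res_limit)
    if (!is.na(cutoff)) rs <- apply_resolution_cutoff(rs, cutoff)
    for (pv in providers) {
      tseed <- (rng_seed * 1000L + si * 10L +
                  match(pv, c("true", "noisy", "random"))) %% .Machine$integer.max
      seed <- make_seed(rs, pv, flip_fraction = flip_fraction, rng_seed = tseed)
      sol <- solve_structure(rs, seed, strategy = strategy, rng_seed = tseed, ...)
      out[[length(out) + 1L]] <- trial_record(st, rs, seed, sol,
                                              structure_id = si)
    }
  }
  do.call(rbind, out)
}

#' Resolution cut-off benchmark
#'
#' Runs the full factorial cohort x cutoff x provider experiment, pools all
#' trial records into a single solved/unsolved clustering (so the solvability
#' criterion is shared across cut-offs), and reports the efficiency curve with
#' propagated uncertainty for every provider.
#'
#' @param structures List of structures (fixed cohort).
#' @param cutoffs Numeric vector of cut-offs in angstroms; `NA` means no cut.
#' @param providers Seed providers to compare.
#' @param strategy Phasing strategy.
#' @param res_limit Base resolution of the simulated data.
#' @param flip_fraction Noisy-provider flip fraction.
#' @param rng_seed Integer seed.
#' @param ... Passed to [solve_structure()].
#' @return List with `records` (all trials, plus `cutoff` and `solved`
#'   columns), `curves` (data.frame `cutoff`, `provider`, `E`, `sigma_E`,
#'   `D`, `N`), `clustering` (the pooled [cluster_solved()] result).
#' @export
resolution_benchmark <- function(structures,
                                 cutoffs = c(NA, 1.0, 1.2, 1.4, 1.6),
                                 providers = c("true", "noisy", "random"),
                                 strategy = "seed", res_limit = 0.9,
                                 flip_fraction = 0.1, rng_seed = 1, ...) {
  recs <- list()
  for (ci in seq_along(cutoffs)) {
    r <- run_cohort(structures, providers = providers, strategy = strategy,
                    res_limit = res_limit, cutoff = cutoffs[ci],
                    flip_fraction = flip_fraction,
                    rng_seed = rng_seed + ci, ...)
    r$cutoff <- cutoffs[ci]
    recs[[ci]] <- r
  }
  records <- do.call(rbind, recs)
  cl <- cluster_solved(records, rng_seed = rng_seed)
  records$solved <- cl$solved
  curves <- do.call(rbind, lapply(seq_along(cutoffs), function(ci) {
    do.call(rbind, lapply(providers, function(pv) {
      sel <- records$provider == pv |
        (pv == "noisy" & startsWith(records$provider, "noisy"))
      sel <- sel & (is.na(cutoffs[ci]) & is.na(records$cutoff) |
                      !is.na(records$cutoff) & !is.na(cutoffs[ci]) &
                      records$cutoff == cutoffs[ci])
      eff <- efficiency(sum(records$solved[sel]), sum(sel))
      data.frame(cutoff = cutoffs[ci], provider = pv, E = eff$E,
                 sigma_E = eff$sigma_E, D = eff$D, N = eff$N)
    }))
  }))
  list(records = records, curves = curves, clustering = cl)
}
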