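# Surface-exposure classification from enzyme-treatment differentials and
# neural-gas clustering of kinetic fold-change profiles.

#' Classify surface-exposed glycosites
#'
#' A site is called affected by a treatment when at least two of its
#' glycoforms change significantly; sites with a single significant glycoform
#' are reported but flagged unaffected.
#'
#' @param diff Differential result table (one contrast) from
#'   [differential()].
#' @param site_map Data frame mapping `feature` to `protein` and
#'   `site_position`.
#' @return Data frame per site: `protein`, `site_position`, `n_glycoforms`,
#'   `n_significant_glycoforms`, `affected`.
#' @export
classify_site_exposure <- function(diff, site_map) {
  m <- merge(diff, site_map, by = "feature")
  site <- paste(m$protein, m$site_position, sep = "\r")
  sf <- factor(site, levels = unique(site))
  first <- !duplicated(sf)
  out <- data.frame(protein = m$protein[first],
                    site_position = m$site_position[first],
                    n_glycoforms = as.integer(table(sf)[levels(sf)]),
                    n_significant_glycoforms = as.integer(
                      tapply(m$significant, sf, sum)),
                    stringsAsFactors = FALSE)
  out$affected <- out$n_significant_glycoforms >= 2L
  rownames(out) <- NULL
  out
}

#' Composition-level exposure counts and cross-treatment agreement
#'
#' Per glycan composition, counts how many glycopeptides carrying it changed
#' significantly under each of two treatments, and quantifies agreement as
#' (i) the Pearson correlation of the two per-composition count vectors and
#' (ii) the Pearson correlation of log2 fold changes of shared glycopeptides
#' restricted to sites called affected (at least two significant glycoforms)
#' under both treatments.
#'
#' @param diff_a,diff_b Differential result tables for the two treatments.
#' @param features Data frame per feature: `feature`, `composition`,
#'   `protein`, `site_position`.
#' @return List: `counts` (per composition, `n_significant_a`,
#'   `n_significant_b`), `count_correlation`, `fc_correlation`,
#'   `n_shared_features`.
#' @export
composition_exposure_counts <- function(diff_a, diff_b, features) {
  cnt <- function(diff) {
    m <- merge(diff[diff$significant, , drop = FALSE], features,
               by = "feature")
    table(factor(m$composition, levels = sort(unique(features$composition))))
  }
  ca <- cnt(diff_a); cb <- cnt(diff_b)
  counts <- data.frame(composition = names(ca),
                       n_significant_a = as.integer(ca),
                       n_significant_b = as.integer(cb),
                       stringsAsFactors = FALSE)
  count_cor <- if (stats::sd(counts$n_significant_a) == 0 ||
                   stats::sd(counts$n_significant_b) == 0) NA_real_ else
    stats::cor(counts$n_significant_a, counts$n_significant_b)
  exp_a <- classify_site_exposure(diff_a, features)
  exp_b <- classify_site_exposure(diff_b, features)
  both <- merge(exp_a[exp_a$affected, c("protein", "site_position")],
                exp_b[exp_b$affected, c("protein", "site_position")])
  shared <- merge(merge(diff_a, diff_b, by = "feature",
                        suffixes = c("_a", "_b")),
                  features, by = "feature")
  shared <- merge(shared, both, by = c("protein", "site_position"))
  fc_cor <- if (nrow(shared) >= 3L &&
                stats::sd(shared$log2_fc_a) > 0 &&
                stats::sd(shared$log2_fc_b) > 0) {
    stats::cor(shared$log2_fc_a, shared$log2_fc_b)
  } else NA_real_
  list(counts = counts, count_correlation = count_cor,
       fc_correlation = fc_cor, n_shared_features = nrow(shared))
}

#' Neural gas vector quantization
#'
#' Rank-based online vector quantization. Prototypes are initialized by
#' sampling `k` distinct input vectors; at each of `t_max` adaptation steps
#' one input is presented (shuffled cyclic order), prototypes are ranked by
#' Euclidean distance to it (0-based rank `r`), and every prototype moves by
#' `epsilon(t) * exp(-r / lambda(t)) * (x - w)`. Both the learning rate
#' `epsilon` and the neighborhood range `lambda` decay exponentially from
#' their initial to their final value, reaching the final value exactly at
#' `t_max`. The run is deterministic given `seed`.
#'
#' @param x Numeric matrix of profiles, observations x dimensions.
#' @param k Number of prototypes (at most the number of distinct profiles).
#' @param epsilon_initial,epsilon_final Learning-rate schedule endpoints
#'   (`0 < epsilon_final <= epsilon_initial < 1`).
#' @param lambda_initial,lambda_final Neighborhood-range schedule endpoints
#'   (both > 0); default `lambda_initial = k / 2`.
#' @param t_max Number of adaptation steps (default `100 * nrow(x)`).
#' @param seed Random seed.
#' @param restarts Number of seeded restarts (`seed`, `seed + 1`, ...); the
#'   run with the lowest quantization error is returned (default 1).
#' @return List of class `neural_gas`: `prototypes` (k x dimensions),
#'   `cluster` (nearest-prototype assignment per observation),
#'   `quant_error` (mean squared distance to the assigned prototype),
#'   `config`.
#' @export
neural_gas <- function(x, k, epsilon_initial = 0.5, epsilon_final = 0.005,
                       lambda_initial = k / 2, lambda_final = 0.01,
                       t_max = NULL, seed = 1L, restarts = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(t_max)) t_max <- 100L * n
  if (!(epsilon_final > 0 && epsilon_final <= epsilon_initial &&
        epsilon_initial < 1)) {
    stop("need 0 < epsilon_final <= epsilon_initial < 1")
  }
  if (lambda_initial <= 0 || lambda_final <= 0 || t_max < 1L) {
    stop("lambda values must be > 0 and t_max >= 1")
  }
  distinct <- !duplicated(x)
  if (k > sum(distinct)) stop("k exceeds the number of distinct profiles")
  fits <- lapply(seq_len(restarts) - 1L, function(off)
    .neural_gas_once(x, k, epsilon_initial, epsilon_final, lambda_initial,
                     lambda_final, t_max, seed + off, distinct))
  fits[[which.min(vapply(fits, `[[`, numeric(1), "quant_error"))]]
}

.neural_gas_once <- function(x, k, epsilon_initial, epsilon_final,
                             lambda_initial, lambda_final, t_max, seed,
                             distinct) {
  n <- nrow(x); d <- ncol(x)
  tx <- t(x)  # dimensions x observations: recycling-friendly layout
  local_seed(seed, {
    w <- tx[, sample(which(distinct), k), drop = FALSE]
    order_idx <- unlist(lapply(seq_len(ceiling(t_max / n)),
                               function(i) sample.int(n)))[seq_len(t_max)]
    ratio_e <- epsilon_final / epsilon_initial
    ratio_l <- lambda_final / lambda_initial
    r <- integer(k)
    for (t in seq_len(t_max)) {
      xi <- tx[, order_idx[t]]
      delta <- xi - w
      r[order(.colSums(delta * delta, d, k))] <- seq_len(k) - 1L
      eps <- epsilon_initial * ratio_e^(t / t_max)
      lam <- lambda_initial * ratio_l^(t / t_max)
      w <- w + delta * rep(eps * exp(-r / lam), each = d)
    }
    d2 <- vapply(seq_len(k),
                 function(j) .colSums((tx - w[, j])^2, d, n), numeric(n))
    d2 <- matrix(d2, nrow = n)
    cluster <- max.col(-d2, ties.method = "first")
    qe <- mean(d2[cbind(seq_len(n), cluster)])
    w <- t(w)
    dimnames(w) <- list(paste0("prototype_", seq_len(k)), colnames(x))
    structure(list(prototypes = w, cluster = cluster, quant_error = qe,
                   config = list(k = k, epsilon_initial = epsilon_initial,
                                 epsilon_final = epsilon_final,
                                 lambda_initial = lambda_initial,
                                 lambda_final = lambda_final,
                                 t_max = t_max, seed = seed)),
              class = "neural_gas")
  })
}

#' Cluster kinetic fold-change profiles
#'
#' Selects features significantly regulated at one or more time points,
#' arranges their per-time log2 fold changes as profiles, and clusters them
#' with [neural_gas()]. The fucosylation-focused variant restricts to
#' fucosylated-class features with a significant negative fold change at one
#' or more time points.
#'
#' @param diff Differential result table with one contrast per time point.
#' @param k Number of clusters (4 for all regulated features; 3 for the
#'   fucosylated, ever-downregulated subset).
#' @param select `"regulated"` (default) or `"fucosylated_down"`.
#' @param classes Named character vector of glycan classes per feature
#'   (required for `"fucosylated_down"`).
#' @param standardize If `TRUE`, z-score each profile before clustering
#'   (default `FALSE`: raw log2 fold changes are clustered).
#' @param seed Random seed passed to [neural_gas()].
#' @param t_max Adaptation steps (default `1000 * n` profiles: kinetic
#'   prototype shapes can lie close together and benefit from a longer
#'   annealing schedule than the generic default).
#' @param restarts Seeded [neural_gas()] restarts, best run kept (default 3).
#' @param ... Further arguments to [neural_gas()].
#' @return List: `membership` (data frame feature, cluster), `prototypes`,
#'   `cluster_means` (mean observed profile per cluster), `fit` (the
#'   [neural_gas()] object), `profiles` (the clustered matrix).
#' @export
cluster_kinetics <- function(diff, k = 4L,
                             select = c("regulated", "fucosylated_down"),
                             classes = NULL, standardize = FALSE,
                             seed = 1L, t_max = NULL, restarts = 3L, ...) {
  select <- match.arg(select)
  times <- unique(diff$contrast)
  wide <- matrix(NA_real_, nrow = length(unique(diff$feature)),
                 ncol = length(times),
                 dimnames = list(unique(diff$feature), times))
  wide[cbind(match(diff$feature, rownames(wide)),
             match(diff$contrast, times))] <- diff$log2_fc
  sig <- matrix(FALSE, nrow(wide), ncol(wide), dimnames = dimnames(wide))
  sig[cbind(match(diff$feature, rownames(wide)),
            match(diff$contrast, times))] <- diff$significant
  keep <- rowSums(sig) >= 1L
  if (select == "fucosylated_down") {
    if (is.null(classes)) stop("'classes' is required for fucosylated_down")
    fuc <- names(classes)[classes %in% c("fucosylated", "o_fucosylated")]
    down <- rowSums(sig & wide < 0, na.rm = TRUE) >= 1L
    keep <- keep & down & rownames(wide) %in% fuc
  }
  profiles <- wide[keep & stats::complete.cases(wide), , drop = FALSE]
  if (nrow(profiles) < k) stop("fewer regulated features than clusters")
  zin <- if (standardize) t(scale(t(profiles))) else profiles
  # kinetic prototype shapes can lie close together; a longer annealing
  # schedule plus restarts avoids dead prototypes between nearby clusters
  if (is.null(t_max)) t_max <- 1000L * nrow(zin)
  fit <- neural_gas(zin, k, seed = seed, t_max = t_max,
                    restarts = restarts, ...)
  means <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(profiles[fit$cluster == j, , drop = FALSE])
  }))
  rownames(means) <- paste0("cluster_", seq_len(k))
  list(membership = data.frame(feature = rownames(profiles),
                               cluster = fit$cluster,
                               stringsAsFactors = FALSE),
       prototypes = fit$prototypes, cluster_means = means, fit = fit,
       profiles = profiles)
}
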