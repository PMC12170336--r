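# Synthetic glycoproteomics data with full ground truth: glyco-PSM tables,
# protein tables, designs and per-template experiment matrices emulating the
# statistical structure the downstream analyses assume.

#' Simulation configuration
#'
#' Default values define the study conditions the generator emulates:
#' heavy-tailed glycoforms-per-site counts (a zero-truncated two-component
#' mixture placing half of the sites at 1-2 glycoforms with an overall mean
#' of 17.4), compositions drawn from the database-filter-consistent universe,
#' sparse Dirichlet fractional abundances, log-normal protein abundances,
#' multiplicative log-normal intensity noise, reporter channel leak injected
#' below the 1/16 masking boundary, and per-template effect sizes.
#'
#' @param seed Random seed (mandatory).
#' @param ... Overrides for any default listed below.
#' @return Named list of simulation parameters.
#' @export
sim_config <- function(seed, ...) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    # glycoproteome structure
    n_proteins = 40L,
    sites_per_protein_lambda = 1.2,
    gf_p_low = 0.5,       # P(site has 1-2 glycoforms)
    gf_p_one = 0.6,       # P(1 | low component)
    gf_tail_size = 0.6,   # negative-binomial tail: 3 + NB(size, mu)
    gf_tail_mu = 30.4,    # overall mean = 0.5*1.4 + 0.5*33.4 = 17.4
    share_prob = 0.5,     # within-protein composition sharing
    dirichlet_conc = 0.5, # sparsity of per-site fractional abundances
    protein_meanlog = log(1e7),
    protein_sdlog = 1,
    n_channels = 6L,
    noise_sd = 0.1,       # log2-scale intensity noise
    leak_rate = 0.05,     # fraction of reporter cells replaced by leak
    q_fail_rate = 0.05,   # PSMs with glycan q above 0.05
    unmodified_rate = 0.02,
    psm_extra_lambda = 0.3,
    # two-group / surface template
    n_features = 1000L, n_per_group = 3L,
    effect_fraction = 0, effect_lfc = 2,
    # time-course template
    times = c("6h", "24h", "48h", "72h"),
    n_regulated = 200L, n_null = 100L,
    # tissue template
    tissues = c("brain", "liver", "kidney"),
    n_sites = 50L, glycopeptides_per_site = 8L, n_replicates = 3L,
    divergence_fraction = 0.2, profile_noise_sd = 0.05,
    # surface template
    exposure_prob_high_mannose = 0.25, exposure_prob_other = 0.7,
    exposed_site_fraction = 0.5, exposure_lfc = -1.5,
    # solubility template
    solubility_shift = 1.5, solubility_shift_fraction = 0.1,
    solubility_replicates = 4L,
    # melt template
    melt_temperatures = seq(40.4, 66.3, length.out = 9),
    melt_plateau = 0.1, melt_width = 2.5, melt_tm_mean = 50,
    melt_tm_sd = 3, melt_delta_tm = -2, melt_shift_fraction = 0.25,
    melt_sets = 3L, melt_noise_sd = 0.05)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  stopifnot(cfg$gf_p_low >= 0, cfg$gf_p_low <= 1,
            cfg$share_prob >= 0, cfg$share_prob <= 1,
            cfg$leak_rate >= 0, cfg$leak_rate <= 1)
  cfg
}

# Heavy-tailed glycoforms-per-site counts: zero-truncated mixture of a
# {1,2} component and a shifted negative-binomial tail.
r_glycoform_count <- function(n, cfg) {
  low <- stats::rbinom(n, 1L, cfg$gf_p_low) == 1L
  k <- integer(n)
  k[low] <- ifelse(stats::runif(sum(low)) < cfg$gf_p_one, 1L, 2L)
  k[!low] <- 3L + stats::rnbinom(sum(!low), size = cfg$gf_tail_size,
                                 mu = cfg$gf_tail_mu)
  k
}

# Enumerated composition universe consistent with the database filter rules,
# with sampling weights favoring simpler compositions.
composition_universe <- function() {
  g <- expand.grid(hexnac = 1:6, hex = 0:10, fuc = 0:3, neuac = 0:3,
                   neugc = 0:1, phospho = 0:1, sulfo = 0L)
  flags <- filter_database(g)
  u <- flags[flags$retained, c(glycan_residues, "composition"), drop = FALSE]
  u$weight <- exp(-rowSums(u[, glycan_residues]) / 4)
  u
}

# Random amino-acid peptide containing an N at the glycosite offset.
r_peptide <- function(n, site_offset = 4L, len = 10L) {
  aa <- strsplit("ACDEFGHIKLMQRVWY", "")[[1L]]  # no N/P/S/T by default
  vapply(seq_len(n), function(i) {
    p <- sample(aa, len, replace = TRUE)
    p[site_offset] <- "N"
    paste(p, collapse = "")
  }, character(1))
}

#' Simulate a glycoproteome PSM export with ground truth
#'
#' Generates a glyco-PSM table and matching protein table in the dialect
#' read by [read_psm_table()]. Sites get heavy-tailed glycoform counts;
#' compositions always satisfy the database filter rules; within-protein
#' composition sharing is planted at `share_prob`; intensities are protein
#' abundance times sparse Dirichlet fractional abundances times log-normal
#' noise; reporter channel leak is injected at `leak_rate` strictly below
#' the 1/16 masking boundary; a small fraction of PSMs carry failing glycan
#' q-values or no glycan (to exercise the identification filters). The
#' output is deterministic under the config seed.
#'
#' @param config A [sim_config()] list.
#' @return List: `psms` (PSM data frame, standardized columns), `proteins`
#'   (protein table with channel columns), `design`, `truth` (per-feature
#'   and per-site ground truth, leak positions), `config`.
#' @export
simulate_glycoproteome <- function(config) {
  cfg <- config
  universe <- composition_universe()
  local_seed(cfg$seed, {
    channels <- sprintf("%02d", seq_len(cfg$n_channels))
    abund <- stats::rlnorm(cfg$n_proteins, cfg$protein_meanlog,
                           cfg$protein_sdlog)
    proteins <- sprintf("PROT%03d", seq_len(cfg$n_proteins))
    n_sites <- 1L + stats::rpois(cfg$n_proteins,
                                 cfg$sites_per_protein_lambda)
    if (cfg$share_prob > 0 && all(n_sites == 1L)) {
      stop("composition sharing is infeasible: every protein has one site")
    }
    feat <- list(); site_rows <- list()
    for (pi in seq_len(cfg$n_proteins)) {
      prev_comps <- character(0)
      positions <- sort(sample(20:600, n_sites[pi]))
      for (si in seq_len(n_sites[pi])) {
        m <- min(r_glycoform_count(1L, cfg), nrow(universe) %/% 2L)
        comps <- character(0)
        for (j in seq_len(m)) {
          pool <- setdiff(prev_comps, comps)
          comps[j] <- if (length(pool) > 0L &&
                          stats::runif(1) < cfg$share_prob) {
            sample(pool, 1L)
          } else {
            fresh <- !(universe$composition %in% comps)
            sample(universe$composition[fresh], 1L,
                   prob = universe$weight[fresh])
          }
        }
        prev_comps <- unique(c(prev_comps, comps))
        frac <- stats::rgamma(m, cfg$dirichlet_conc)
        frac <- frac / sum(frac)
        feat[[length(feat) + 1L]] <- data.frame(
          protein = proteins[pi], site_position = positions[si],
          peptide = r_peptide(1L), composition = comps,
          true_fraction = frac,
          ms1_intensity = abund[pi] * frac *
            2^stats::rnorm(m, 0, cfg$noise_sd),
          stringsAsFactors = FALSE)
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          protein = proteins[pi], site_position = positions[si],
          n_glycoforms = m, stringsAsFactors = FALSE)
      }
    }
    features <- do.call(rbind, feat)
    features$feature <- paste(features$peptide, features$composition,
                              sep = "|")
    nf <- nrow(features)
    base <- features$ms1_intensity / cfg$n_channels
    rep_mat <- base * matrix(2^stats::rnorm(nf * cfg$n_channels, 0,
                                            cfg$noise_sd),
                             nf, cfg$n_channels)
    leak <- matrix(stats::runif(nf * cfg$n_channels) < cfg$leak_rate,
                   nf, cfg$n_channels)
    if (any(leak)) {
      mx <- apply(rep_mat, 1L, max)
      leak_val <- rep(mx, cfg$n_channels)[leak] *
        stats::runif(sum(leak), 0, 0.95 / 16)
      rep_mat[leak] <- leak_val
    }
    colnames(rep_mat) <- paste0("channel_", channels)
    # expand glycopeptides to PSMs
    n_psms <- 1L + stats::rpois(nf, cfg$psm_extra_lambda)
    idx <- rep(seq_len(nf), n_psms)
    psms <- features[idx, c("peptide", "protein", "site_position",
                            "composition"), drop = FALSE]
    first_of <- !duplicated(idx)
    psms$glycan_q <- ifelse(stats::runif(length(idx)) < cfg$q_fail_rate,
                            stats::runif(length(idx), 0.0501, 0.3),
                            stats::runif(length(idx), 0, 0.05))
    psms$ms1_intensity <- features$ms1_intensity[idx] *
      ifelse(first_of, 1, stats::runif(length(idx), 0.3, 0.9))
    psms$spectrum_id <- sprintf("spec_%05d", seq_along(idx))
    psms$peptide_start <- pmax(1L, psms$site_position - 3L)
    rep_expand <- rep_mat[idx, , drop = FALSE] / n_psms[idx]
    for (j in seq_len(ncol(rep_mat))) {
      psms[[colnames(rep_mat)[j]]] <- rep_expand[, j]
    }
    # unmodified peptides (no glycan assignment)
    n_un <- stats::rpois(1L, cfg$unmodified_rate * nf)
    if (n_un > 0L) {
      un <- psms[sample(nrow(psms), n_un), , drop = FALSE]
      un$composition <- ""
      un$spectrum_id <- sprintf("spec_un%04d", seq_len(n_un))
      psms <- rbind(psms, un)
    }
    rownames(psms) <- NULL
    prot_tab <- data.frame(protein = proteins, abundance = abund,
                           stringsAsFactors = FALSE)
    for (j in seq_len(cfg$n_channels)) {
      prot_tab[[paste0("channel_", channels[j])]] <-
        abund / cfg$n_channels *
        2^stats::rnorm(cfg$n_proteins, 0, cfg$noise_sd)
    }
    design <- data.frame(channel = channels,
                         condition = "baseline",
                         replicate = seq_len(cfg$n_channels),
                         stringsAsFactors = FALSE)
    structure(list(
      psms = structure(psms, mode = "N", channels = channels),
      proteins = prot_tab, design = design,
      truth = list(features = features,
                   sites = do.call(rbind, site_rows),
                   leak = leak, n_unmodified = n_un),
      config = cfg), class = "glyco_simulation")
  })
}

#' Simulate a designed quantification experiment with ground truth
#'
#' Each template mirrors one perturbation design: `two_group` plants log2
#' fold changes on a configured fraction of features; `time_course` assigns
#' regulated features to one of four kinetic prototype curves (early
#' plateau, late plateau, transient, gradual monotone); `tissues` plants
#' divergent site glycosylation profiles on a configured fraction of sites;
#' `surface` plants abundance drops on surface-exposed glycoforms with
#' class-dependent probability (high mannose less exposed); `solubility`
#' plants glycoform-specific NP40/SDS ratio shifts; `melt` generates 9-point
#' sigmoidal melting series with a planted melting-point shift for a protein
#' subset and per-set batch factors.
#'
#' @param template One of `"two_group"`, `"time_course"`, `"tissues"`,
#'   `"surface"`, `"solubility"`, `"melt"`.
#' @param config A [sim_config()] list.
#' @return List with template-specific matrices, `design`, `truth` and
#'   `config`. See the vignette for each template's layout.
#' @export
simulate_experiment <- function(template = c("two_group", "time_course",
                                             "tissues", "surface",
                                             "solubility", "melt"),
                                config) {
  template <- match.arg(template)
  cfg <- config
  out <- local_seed(cfg$seed + 1L, switch(template,
    two_group = .sim_two_group(cfg),
    time_course = .sim_time_course(cfg),
    tissues = .sim_tissues(cfg),
    surface = .sim_surface(cfg),
    solubility = .sim_solubility(cfg),
    melt = .sim_melt(cfg)))
  out$template <- template
  out$config <- cfg
  out
}

.sim_two_group <- function(cfg) {
  n <- cfg$n_features; r <- cfg$n_per_group
  base <- stats::rnorm(n, 20, 1.5)
  effect <- rep(0, n)
  n_eff <- round(cfg$effect_fraction * n)
  if (n_eff > 0L) {
    idx <- sample(n, n_eff)
    effect[idx] <- cfg$effect_lfc * sample(c(-1, 1), n_eff, replace = TRUE)
  }
  x <- cbind(matrix(base, n, r) ,
             matrix(base + effect, n, r)) +
    matrix(stats::rnorm(n * 2 * r, 0, cfg$noise_sd), n, 2 * r)
  rownames(x) <- sprintf("gp%04d", seq_len(n))
  design <- data.frame(condition = rep(c("control", "treated"), each = r),
                       replicate = rep(seq_len(r), 2L),
                       stringsAsFactors = FALSE)
  list(glyco = x, design = design,
       truth = list(effect = stats::setNames(effect, rownames(x))))
}

.kinetic_prototypes <- function(times) {
  n_t <- length(times)
  tt <- seq_len(n_t) / n_t
  rbind(plateau_early = rep(-2, n_t),
        plateau_late = -2 / (1 + exp(-12 * (tt - 0.6))),
        transient = -2 * exp(-((tt - 0.25) / 0.22)^2),
        monotone = -2 * tt)
}

.sim_time_course <- function(cfg) {
  times <- cfg$times; r <- cfg$n_per_group
  protos <- .kinetic_prototypes(times)
  n_reg <- cfg$n_regulated; n0 <- cfg$n_null
  n <- n_reg + n0
  cluster <- c(sample(rep_len(seq_len(nrow(protos)), n_reg)), rep(0L, n0))
  effects <- matrix(0, n, length(times))
  effects[cluster > 0L, ] <- protos[cluster[cluster > 0L], ]
  base <- stats::rnorm(n, 20, 1.5)
  cols <- expand.grid(replicate = seq_len(r), time = times,
                      treatment = c("control", "treated"),
                      stringsAsFactors = FALSE)
  x <- vapply(seq_len(nrow(cols)), function(j) {
    eff <- if (cols$treatment[j] == "treated") {
      effects[, match(cols$time[j], times)]
    } else 0
    base + eff + stats::rnorm(n, 0, cfg$noise_sd)
  }, numeric(n))
  rownames(x) <- sprintf("gp%04d", seq_len(n))
  design <- data.frame(condition = paste(cols$treatment, cols$time,
                                         sep = "_"),
                       treatment = cols$treatment, time = cols$time,
                       replicate = cols$replicate, stringsAsFactors = FALSE)
  classes <- stats::setNames(
    ifelse(cluster > 0L & stats::runif(n) < 0.8, "fucosylated",
           sample(c("sialylated", "high_mannose", "complex_hybrid"), n,
                  replace = TRUE)),
    rownames(x))
  list(glyco = x, design = design,
       truth = list(cluster = stats::setNames(cluster, rownames(x)),
                    prototypes = protos, classes = classes))
}

.sim_tissues <- function(cfg) {
  ts <- cfg$tissues; n_s <- cfg$n_sites; gp <- cfg$glycopeptides_per_site
  r <- cfg$n_replicates
  divergent <- stats::runif(n_s) < cfg$divergence_fraction
  site_total <- stats::rlnorm(n_s, cfg$protein_meanlog, cfg$protein_sdlog)
  rdir <- function(k, conc) { g <- stats::rgamma(k, conc); g / sum(g) }
  features <- data.frame(
    feature = sprintf("gp%04d", seq_len(n_s * gp)),
    protein = rep(sprintf("PROT%03d", seq_len(n_s)), each = gp),
    site_position = rep(100L, n_s * gp),
    stringsAsFactors = FALSE)
  x <- matrix(NA_real_, n_s * gp, length(ts) * r)
  design <- expand.grid(replicate = seq_len(r), tissue = ts,
                        stringsAsFactors = FALSE)[, c("tissue", "replicate")]
  for (si in seq_len(n_s)) {
    base_profile <- rdir(gp, 1)
    rows <- (si - 1L) * gp + seq_len(gp)
    for (tt in seq_along(ts)) {
      profile <- if (divergent[si]) rdir(gp, 0.3) else base_profile
      for (rr in seq_len(r)) {
        j <- (tt - 1L) * r + rr
        x[rows, j] <- site_total[si] * profile *
          exp(stats::rnorm(gp, 0, cfg$profile_noise_sd))
      }
    }
  }
  rownames(x) <- features$feature
  proteins <- unique(features$protein)
  prot <- matrix(stats::rlnorm(length(proteins) * ncol(x),
                               cfg$protein_meanlog, 0.3),
                 length(proteins), ncol(x), dimnames = list(proteins, NULL))
  list(glyco = x, protein = prot,
       match = stats::setNames(features$protein, features$feature),
       design = design, features = features,
       truth = list(divergent = stats::setNames(
         divergent, sprintf("PROT%03d", seq_len(n_s)))))
}

.sim_surface <- function(cfg) {
  universe <- composition_universe()
  n_s <- cfg$n_sites; r <- cfg$n_per_group
  gp_counts <- pmax(2L, pmin(6L, r_glycoform_count(n_s, cfg)))
  n <- sum(gp_counts)
  site_of <- rep(seq_len(n_s), gp_counts)
  comp <- sample(universe$composition, n, replace = TRUE,
                 prob = universe$weight)
  cls <- as.character(classify_n(comp))
  site_exposed <- stats::runif(n_s) < cfg$exposed_site_fraction
  p_exp <- ifelse(cls == "high_mannose", cfg$exposure_prob_high_mannose,
                  cfg$exposure_prob_other)
  exposed <- site_exposed[site_of] & stats::runif(n) < p_exp
  base <- stats::rnorm(n, 20, 1.5)
  mk <- function() {
    eff <- ifelse(exposed, cfg$exposure_lfc, 0)
    x <- cbind(matrix(base, n, r), matrix(base + eff, n, r)) +
      matrix(stats::rnorm(n * 2 * r, 0, cfg$noise_sd), n, 2 * r)
    rownames(x) <- sprintf("gp%04d", seq_len(n))
    x
  }
  design <- data.frame(condition = rep(c("control", "treated"), each = r),
                       replicate = rep(seq_len(r), 2L),
                       stringsAsFactors = FALSE)
  features <- data.frame(feature = sprintf("gp%04d", seq_len(n)),
                         composition = comp,
                         protein = sprintf("PROT%03d", site_of),
                         site_position = 100L, class = cls,
                         stringsAsFactors = FALSE)
  list(glyco_pngase = mk(), glyco_protk = mk(), design = design,
       features = features,
       truth = list(exposed = stats::setNames(exposed, features$feature),
                    site_exposed = site_exposed))
}

.sim_solubility <- function(cfg) {
  n_p <- cfg$n_proteins; r <- cfg$solubility_replicates
  gf_per_prot <- pmax(1L, pmin(8L, r_glycoform_count(n_p, cfg)))
  n <- sum(gf_per_prot)
  prot_of <- rep(sprintf("PROT%03d", seq_len(n_p)), gf_per_prot)
  prot_ratio_true <- stats::setNames(
    stats::rnorm(n_p, 0, 0.5), sprintf("PROT%03d", seq_len(n_p)))
  shifted <- stats::runif(n) < cfg$solubility_shift_fraction
  shift <- ifelse(shifted, cfg$solubility_shift, 0)
  glyco <- matrix(prot_ratio_true[prot_of] + shift, n, r) +
    matrix(stats::rnorm(n * r, 0, cfg$noise_sd), n, r)
  rownames(glyco) <- sprintf("gf%04d", seq_len(n))
  protein <- matrix(prot_ratio_true, n_p, r) +
    matrix(stats::rnorm(n_p * r, 0, cfg$noise_sd), n_p, r)
  rownames(protein) <- names(prot_ratio_true)
  list(glyco_ratio = glyco, protein_ratio = protein,
       match = stats::setNames(prot_of, rownames(glyco)),
       truth = list(shift = stats::setNames(shift, rownames(glyco))))
}

.sim_melt <- function(cfg) {
  n_p <- cfg$n_proteins
  temps <- cfg$melt_temperatures
  proteins <- sprintf("PROT%03d", seq_len(n_p))
  tm <- stats::rnorm(n_p, cfg$melt_tm_mean, cfg$melt_tm_sd)
  shifted <- stats::runif(n_p) < cfg$melt_shift_fraction
  d_tm <- ifelse(shifted, cfg$melt_delta_tm, 0)
  abund <- stats::rlnorm(n_p, log(1e6), 0.5)
  set_scale <- stats::rlnorm(cfg$melt_sets, 0, 0.4)
  sigmoid <- function(tt, tm_i) {
    cfg$melt_plateau + (1 - cfg$melt_plateau) /
      (1 + exp((tt - tm_i) / cfg$melt_width))
  }
  grid <- expand.grid(protein = proteins, set = seq_len(cfg$melt_sets),
                      condition = c("reference", "treated"),
                      temperature = temps, stringsAsFactors = FALSE)
  tm_use <- tm[match(grid$protein, proteins)] +
    ifelse(grid$condition == "treated",
           d_tm[match(grid$protein, proteins)], 0)
  grid$intensity <- abund[match(grid$protein, proteins)] *
    sigmoid(grid$temperature, tm_use) *
    set_scale[grid$set] *
    exp(stats::rnorm(nrow(grid), 0, cfg$melt_noise_sd))
  list(melt = grid,
       truth = list(delta_tm = stats::setNames(d_tm, proteins),
                    tm = stats::setNames(tm, proteins),
                    set_scale = set_scale))
}
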