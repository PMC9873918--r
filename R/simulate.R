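# Synthetic time-course colitis data with planted structure. The generator
# emulates the DSS hit/rest design: two groups (disease, control) sampled at
# days 5, 12, 17 and 36, negative-binomial gene and exon counts, planted
# timepoint-specific effects, five trajectory classes, isoform switches, VDJ
# clone tables whose burden tracks severity, and histology scores driven by
# a latent per-sample severity.

#' Canonical trajectory class shapes
#'
#' Unit-scale disease-trajectory templates over the four sacrifice days:
#' A early (high days 5+12), B late (progressive increase), C very-early
#' (day-5 peak), D day-12 up, E day-12 down.
#'
#' @param days day vector (used only for column names).
#' @return 5 x length(days) matrix, rownames A..E.
#' @export
canonical_trajectory_shapes <- function(days = c(5, 12, 17, 36)) {
  shapes <- rbind(
    A = c(1, 1, 0, 0),
    B = c(0, 1 / 3, 2 / 3, 1),
    C = c(1, 0, 0, 0),
    D = c(0, 1, 0, 0),
    E = c(0, -1, 0, 0)
  )
  colnames(shapes) <- as.character(days)
  shapes
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic cohort. Defaults
#' describe the study conditions: 2 groups x 4 days x 10 mice, ~0.1 mean NB
#' dispersion, 1e7 gene-level and 1e6 exon-level library sizes, planted
#' per-day fixed effects (log2 effect 2), five trajectory clusters shaped
#' like the canonical classes, isoform switches in disease, severity that
#' peaks on DSS hit phases and dips in rest phases.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range (min, max) of counting bins per gene.
#' @param days sacrifice days.
#' @param n_per_group_per_day mice per group per day.
#' @param baseline_log2_mean,baseline_log2_sd normal parameters of baseline
#'   log2 relative expression.
#' @param phi constant NB dispersion; when `NULL`, per-gene dispersions are
#'   gamma-distributed with `dispersion_shape`/`dispersion_rate`.
#' @param dispersion_shape,dispersion_rate gamma parameters of per-gene
#'   dispersion (mean 0.1 by default).
#' @param lib_size_gene,lib_size_exon,lib_size_sdlog log-normal library-size
#'   parameters (medians and sdlog).
#' @param fixed_effect list: `n_per_day` genes planted per day with log2
#'   `effect` (disease vs control at that day only), plus `n_persistent`
#'   genes carrying the effect at every day (disease markers shared across
#'   timepoints; the default ratio of persistent to day-specific genes makes
#'   about 55% of the DE union one-timepoint-specific, the fraction observed
#'   in DSS colitis). Within each
#'   block, `frac_up` (default 0.5) of the genes take `+effect` and the rest
#'   `-effect`, keeping the planted transcriptome compositionally balanced
#'   so that column-sum library sizes stay honest.
#' @param trajectory list: `n_per_cluster` genes per canonical class,
#'   `amplitude` multiplying the unit shapes (log2 scale).
#' @param splice list: `n_genes` isoform-switch genes, log2 `effect` added to
#'   the designated exon subset in disease only, `time_profile` per-day
#'   multiplier of that effect (constant 1 = fixed switch; a ramp makes the
#'   switch time-dependent).
#' @param usage_concentration Dirichlet concentration of per-mouse exon-bin
#'   usage around the gene's baseline proportions; 60 gives inter-individual
#'   usage (PSI) scatter of a few percent, in line with reported splicing
#'   variability. `Inf` disables the extra-multinomial noise.
#' @param vdj list: clone-table parameters (`base_burden`,
#'   `burden_per_severity`, `base_clones`, `clones_per_severity`,
#'   `concentration`, `concentration_decay`, `reads_dispersion`).
#' @param histology list: `weight` and `noise_sd` linking latent severity to
#'   the histology score.
#' @param severity_by_day expected disease severity per day (hit/rest
#'   profile); controls have severity 0.
#' @param severity_cv log-normal coefficient of variation of per-mouse
#'   severity around its day mean.
#' @param cohort,tissue labels stamped into the sample metadata.
#' @param seed integer sampling seed (cohort-level draws).
#' @param structure_seed seed of the gene-level "genome" (baselines,
#'   dispersions, exon-bin structure); cohorts sharing it share genes, bins
#'   and the planted severity link, so cross-cohort transfer is meaningful.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       exons_per_gene = c(4, 10),
                       days = c(5, 12, 17, 36),
                       n_per_group_per_day = 10,
                       baseline_log2_mean = 4,
                       baseline_log2_sd = 2,
                       phi = NULL,
                       dispersion_shape = 2,
                       dispersion_rate = 20,
                       lib_size_gene = 1e7,
                       lib_size_exon = 1e6,
                       lib_size_sdlog = 0.2,
                       fixed_effect = list(n_per_day = 50, effect = 2,
                                           n_persistent = 165, frac_up = 0.5),
                       trajectory = list(n_per_cluster = 40, amplitude = 2),
                       splice = list(n_genes = 30, effect = 1.5,
                                     time_profile = c(1, 1, 1, 1)),
                       usage_concentration = 60,
                       vdj = list(base_burden = 200, burden_per_severity = 100,
                                  base_clones = 80, clones_per_severity = 5,
                                  concentration = 2, concentration_decay = 0.15,
                                  reads_dispersion = 5),
                       histology = list(weight = 1, noise_sd = 0.5),
                       severity_by_day = c(6, 4, 8, 5),
                       severity_cv = 0.25,
                       cohort = "DSS-WC",
                       tissue = "colon",
                       seed = 1,
                       structure_seed = 1000) {
  stopifnot(n_genes > 0, n_per_group_per_day > 0, length(days) >= 2,
            length(exons_per_gene) == 2, exons_per_gene[1] >= 2,
            length(severity_by_day) == length(days),
            length(splice$time_profile) == length(days),
            histology$noise_sd >= 0)
  if (is.null(fixed_effect$n_persistent)) fixed_effect$n_persistent <- 0
  n_planted <- length(days) * fixed_effect$n_per_day +
    fixed_effect$n_persistent + 5 * trajectory$n_per_cluster + splice$n_genes
  if (n_planted > n_genes) {
    stop("planted effect genes exceed n_genes; effect sets must be disjoint")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Latent severity per sample: day profile for disease mice, log-normal
# mouse-level scatter (mean-one multiplier), zero for controls.
.simulate_severity <- function(meta, cfg) {
  sev <- numeric(nrow(meta))
  dis <- meta$group == "disease"
  day_idx <- match(meta$day, cfg$days)
  mult <- exp(stats::rnorm(sum(dis), -cfg$severity_cv^2 / 2, cfg$severity_cv))
  sev[dis] <- cfg$severity_by_day[day_idx[dis]] * mult
  names(sev) <- meta$sample_id
  sev
}

.make_meta <- function(cfg) {
  grid <- expand.grid(i = seq_len(cfg$n_per_group_per_day),
                      group = c("control", "disease"),
                      day = cfg$days, stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("%s_d%02d_%s%02d",
                        gsub("[^A-Za-z0-9]", "", cfg$cohort), grid$day,
                        ifelse(grid$group == "disease", "dis", "ctl"), grid$i),
    group = grid$group, day = grid$day,
    cohort = cfg$cohort, tissue = cfg$tissue,
    stringsAsFactors = FALSE
  )
  validate_sample_meta(meta, allowed_days = cfg$days)
}

# Per-gene planted log2 effect (disease vs control) as a genes x days matrix,
# plus the ground-truth label vector.
.plant_effects <- function(cfg) {
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  n_days <- length(cfg$days)
  delta <- matrix(0, cfg$n_genes, n_days,
                  dimnames = list(gene_ids, as.character(cfg$days)))
  label <- rep("null", cfg$n_genes)
  pos <- 0L
  take <- function(n) {
    idx <- pos + seq_len(n)
    pos <<- pos + n
    idx
  }
  frac_up <- if (is.null(cfg$fixed_effect$frac_up)) 0.5 else
    cfg$fixed_effect$frac_up
  signed <- function(n) {
    n_up <- ceiling(n * frac_up)
    cfg$fixed_effect$effect * rep(c(1, -1), c(n_up, n - n_up))
  }
  for (d in seq_len(n_days)) {
    idx <- take(cfg$fixed_effect$n_per_day)
    delta[idx, d] <- signed(length(idx))
    label[idx] <- sprintf("fixed-day-%d", cfg$days[d])
  }
  n_pers <- if (is.null(cfg$fixed_effect$n_persistent)) 0 else
    cfg$fixed_effect$n_persistent
  if (n_pers > 0) {
    idx <- take(n_pers)
    delta[idx, ] <- matrix(signed(n_pers), n_pers, n_days)
    label[idx] <- "fixed-persistent"
  }
  shapes <- canonical_trajectory_shapes(cfg$days)
  for (cl in rownames(shapes)) {
    idx <- take(cfg$trajectory$n_per_cluster)
    if (length(idx)) {
      delta[idx, ] <- matrix(cfg$trajectory$amplitude * shapes[cl, ],
                             length(idx), n_days, byrow = TRUE)
      label[idx] <- sprintf("cluster-%s", cl)
    }
  }
  splice_idx <- take(cfg$splice$n_genes)
  label[splice_idx] <- "splice"
  list(gene_ids = gene_ids, delta = delta, label = label,
       splice_idx = splice_idx)
}

#' Simulate gene- and exon-level counts with ground truth
#'
#' Gene counts are negative-binomial with mean
#' `mu_gs = L_s * p_g * 2^(x_s * delta_g(day_s) * m_s)` and variance
#' `mu + phi * mu^2`, where `x_s` indicates disease, `delta_g(day)` is the
#' planted log2 effect and `m_s` the mouse's severity relative to its day
#' mean (so the expected day-level effect equals `delta`). Exon counts
#' partition a separate exon-level NB total across Dirichlet-drawn bin
#' proportions; isoform-switch genes shift a designated exon subset in
#' disease only.
#'
#' @param cfg a [sim_config].
#' @return list with elements `gene` and `exon` ([count_matrix]), `annotation`
#'   (exon-to-gene map), `meta` (sample metadata), and `truth` (list:
#'   per-gene `labels` data.frame, per-sample `severity`, planted `delta`
#'   matrix, and `splice_exons` designating switch/other exons).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  meta <- .make_meta(cfg)
  if (!all(table(meta$group, meta$day) > 0)) {
    stop("need disease and control samples at every day")
  }
  plant <- .plant_effects(cfg)
  n_g <- cfg$n_genes
  n_s <- nrow(meta)
  day_idx <- match(meta$day, cfg$days)
  dis <- meta$group == "disease"

  # gene-level "genome": baselines, dispersions, exon-bin structure. Drawn
  # under structure_seed so cohorts simulated with different sampling seeds
  # share the same genes, bins and planted severity link.
  set.seed(cfg$structure_seed)
  base <- stats::rnorm(n_g, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  p_g <- 2^base / sum(2^base)
  phi <- if (!is.null(cfg$phi)) rep(cfg$phi, n_g) else {
    stats::rgamma(n_g, shape = cfg$dispersion_shape, rate = cfg$dispersion_rate)
  }
  phi <- pmax(phi, 1e-8)
  n_exons <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]),
                    n_g, replace = TRUE)
  q_list <- lapply(n_exons, function(e) {
    q <- stats::rgamma(e, shape = 5)
    q / sum(q)
  })

  set.seed(cfg$seed)
  sev <- .simulate_severity(meta, cfg)
  mod <- ifelse(dis, sev / cfg$severity_by_day[day_idx], 0)

  lfc <- plant$delta[, day_idx, drop = FALSE] *
    matrix(mod, n_g, n_s, byrow = TRUE)                     # genes x samples
  lib_gene <- stats::rlnorm(n_s, log(cfg$lib_size_gene), cfg$lib_size_sdlog)
  mu <- (p_g %o% lib_gene) * 2^lfc
  counts <- matrix(
    stats::rnbinom(n_g * n_s, mu = mu, size = rep(1 / phi, n_s)),
    n_g, n_s, dimnames = list(plant$gene_ids, meta$sample_id)
  )
  gene_cm <- count_matrix(counts)

  # exon level: per gene an NB total at exon-scale library size, partitioned
  # across bins; splice genes get disease-specific bin proportions
  lib_exon <- stats::rlnorm(n_s, log(cfg$lib_size_exon), cfg$lib_size_sdlog)
  totals <- matrix(
    stats::rnbinom(n_g * n_s, mu = (p_g %o% lib_exon) * 2^lfc,
                   size = rep(1 / phi, n_s)),
    n_g, n_s
  )
  splice_eff <- numeric(n_g)
  splice_eff[plant$splice_idx] <- cfg$splice$effect
  time_mult <- cfg$splice$time_profile[day_idx]

  exon_rows <- vector("list", n_g)
  ann_rows <- vector("list", n_g)
  for (g in seq_len(n_g)) {
    e <- n_exons[g]
    q <- q_list[[g]]
    probs <- matrix(q, e, n_s)
    if (splice_eff[g] > 0) {
      shift_set <- seq_len(ceiling(e / 2))
      for (s in which(dis)) {
        w <- q
        w[shift_set] <- w[shift_set] * 2^(splice_eff[g] * time_mult[s])
        probs[, s] <- w / sum(w)
      }
    }
    conc <- if (is.null(cfg$usage_concentration)) Inf else
      cfg$usage_concentration
    if (is.finite(conc)) {
      # per-mouse usage scatter: Dirichlet around the expected proportions
      jit <- matrix(stats::rgamma(e * n_s, shape = probs * conc), e, n_s)
      zerocol <- colSums(jit) == 0
      jit[, zerocol] <- probs[, zerocol]
      probs <- sweep(jit, 2, colSums(jit), "/")
    }
    cnt <- matrix(0, e, n_s)
    remaining <- totals[g, ]
    restq <- rep(1, n_s)
    for (j in seq_len(e - 1)) {
      pj <- pmin(1, pmax(0, probs[j, ] / restq))
      x <- stats::rbinom(n_s, remaining, pj)
      cnt[j, ] <- x
      remaining <- remaining - x
      restq <- restq - probs[j, ]
    }
    cnt[e, ] <- remaining
    rownames(cnt) <- sprintf("%s_e%02d", plant$gene_ids[g], seq_len(e))
    exon_rows[[g]] <- cnt
    ann_rows[[g]] <- data.frame(exon_id = rownames(cnt),
                                gene_id = plant$gene_ids[g],
                                bin_index = seq_len(e),
                                stringsAsFactors = FALSE)
  }
  exon_counts <- do.call(rbind, exon_rows)
  colnames(exon_counts) <- meta$sample_id
  annotation <- do.call(rbind, ann_rows)
  annotation <- annotation[order(annotation$exon_id), ]
  rownames(annotation) <- NULL
  exon_cm <- count_matrix(exon_counts)

  splice_exons <- do.call(rbind, lapply(plant$splice_idx, function(g) {
    e <- n_exons[g]
    data.frame(
      gene_id = plant$gene_ids[g],
      exon_id = sprintf("%s_e%02d", plant$gene_ids[g], seq_len(e)),
      isoform = ifelse(seq_len(e) <= ceiling(e / 2), "switch", "other"),
      stringsAsFactors = FALSE
    )
  }))

  truth <- list(
    labels = data.frame(gene_id = plant$gene_ids, label = plant$label,
                        stringsAsFactors = FALSE),
    severity = sev,
    delta = plant$delta,
    splice_exons = splice_exons
  )
  ct_log(sprintf("simulated %d genes / %d exons x %d samples",
                 n_g, nrow(exon_counts), n_s))
  list(gene = gene_cm, exon = exon_cm, annotation = annotation,
       meta = meta, truth = truth)
}

#' Simulate a VDJ clone abundance table
#'
#' Per-sample total VDJ read burden is negative-binomial with mean increasing
#' linearly in severity; reads are spread over a Dirichlet-multinomial clone
#' frequency vector whose concentration decreases with severity, so high
#' severity yields both more VDJ reads and more dominant clones.
#'
#' @param severity named non-negative vector of per-sample latent severities.
#' @param vdj_spec parameter list, see [sim_config()].
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `clone_id`, `reads`
#'   (positive rows only).
#' @export
simulate_vdj <- function(severity, vdj_spec = sim_config()$vdj, seed = 1) {
  if (any(severity < 0)) stop("severities must be >= 0")
  if (is.null(names(severity))) stop("severity must be a named vector")
  set.seed(seed)
  out <- lapply(names(severity), function(s) {
    sev <- severity[[s]]
    k <- 1L + stats::rpois(1, vdj_spec$base_clones +
                             vdj_spec$clones_per_severity * sev)
    total <- stats::rnbinom(
      1, mu = vdj_spec$base_burden + vdj_spec$burden_per_severity * sev,
      size = vdj_spec$reads_dispersion
    )
    alpha <- vdj_spec$concentration /
      (1 + vdj_spec$concentration_decay * sev)
    w <- stats::rgamma(k, shape = alpha)
    if (sum(w) == 0) w <- rep(1, k)
    reads <- as.vector(stats::rmultinom(1, total, w / sum(w)))
    keep <- reads > 0
    if (!any(keep)) return(NULL)
    data.frame(sample_id = s,
               clone_id = sprintf("%s_c%04d", s, which(keep)),
               reads = reads[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Simulate histology scores from latent severity
#'
#' `h_s = max(0, weight * severity_s + Normal(0, noise_sd^2))`.
#'
#' @param severity named non-negative vector.
#' @param weight linear link coefficient.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `histology`.
#' @export
simulate_histology <- function(severity, weight = 1, noise_sd = 0.5, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  h <- pmax(0, weight * severity + stats::rnorm(length(severity), 0, noise_sd))
  data.frame(sample_id = names(severity), histology = unname(h),
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort
#'
#' Runs [simulate_counts()], [simulate_vdj()] and [simulate_histology()] with
#' seeds derived from the config seed, returning everything a downstream
#' analysis consumes.
#'
#' @param cfg a [sim_config].
#' @return list: `gene`, `exon`, `annotation`, `meta`, `truth`, `vdj`
#'   (clone table), `histology`.
#' @export
simulate_experiment <- function(cfg) {
  sim <- simulate_counts(cfg)
  sim$vdj <- simulate_vdj(sim$truth$severity, cfg$vdj, seed = cfg$seed + 1L)
  sim$histology <- simulate_histology(
    sim$truth$severity, weight = cfg$histology$weight,
    noise_sd = cfg$histology$noise_sd, seed = cfg$seed + 2L
  )
  sim
}
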