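#' The combined chemostat + retentostat sampling design
#'
#' Twenty-two arrays: chemostats at mu = 0.2, 0.1, 0.05, 0.03 and
#' 0.025 h^-1 with 3/3/2/3/3 replicates, and retentostat samples at days
#' 2, 9, 16 and 22 (approximate mu 0.0084, 0.0024, 0.0011 and
#' 0.00063 h^-1) in duplicate — nine conditions spanning two and a half
#' orders of magnitude in growth rate.
#'
#' @return sample metadata data.frame: `sample_id`, `mode`,
#'   `growth_rate`, `replicate`, `time_d` (NA for chemostats).
#' @export
design_spec <- function() {
  chem_mu <- c(0.2, 0.1, 0.05, 0.03, 0.025)
  chem_rep <- c(3, 3, 2, 3, 3)
  ret_day <- c(2, 9, 16, 22)
  ret_mu <- c(0.0084, 0.0024, 0.0011, 0.00063)
  chem <- data.frame(
    mode = "chemostat",
    growth_rate = rep(chem_mu, chem_rep),
    replicate = unlist(lapply(chem_rep, seq_len)),
    time_d = NA_real_)
  ret <- data.frame(
    mode = "retentostat",
    growth_rate = rep(ret_mu, each = 2),
    replicate = rep(1:2, length(ret_day)),
    time_d = rep(ret_day, each = 2))
  d <- rbind(chem, ret)
  d$sample_id <- ifelse(d$mode == "chemostat",
                        sprintf("C_mu%g_r%d", d$growth_rate, d$replicate),
                        sprintf("R_d%g_r%d", d$time_d, d$replicate))
  d[, c("sample_id", "mode", "growth_rate", "replicate", "time_d")]
}

#' Replicate-noise settings for the expression generator
#'
#' Noise is multiplicative lognormal with unit mean, parameterised by the
#' coefficient of variation: intensities are positive and replicate
#' scatter in array data is ratio-scaled. The default CV of 0.14 matches
#' typical replicate reproducibility of steady-state cultures;
#' housekeeping genes get a smaller CV (0.10) and are expected to stay
#' below `housekeeping_cv_max` = 0.20.
#'
#' @param replicate_cv replicate CV for responsive/null genes.
#' @param housekeeping_cv replicate CV for housekeeping genes.
#' @param housekeeping_cv_max stability criterion checked downstream.
#' @param seed RNG seed.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(replicate_cv = 0.14, housekeeping_cv = 0.10,
                       housekeeping_cv_max = 0.20, seed = 1) {
  if (replicate_cv < 0 || replicate_cv >= 1 ||
      housekeeping_cv < 0 || housekeeping_cv >= 1)
    stop("CVs must lie in [0, 1)")
  list(replicate_cv = replicate_cv, housekeeping_cv = housekeeping_cv,
       housekeeping_cv_max = housekeeping_cv_max, seed = seed)
}

logistic_ <- function(x, mid, width) 1 / (1 + exp(-(x - mid) / width))

#' Expression archetypes over growth rate
#'
#' Seven smooth profile shapes on log10(mu), emulating the recurring
#' growth-rate response classes of glucose-limited yeast cultures:
#' plateau-then-rise with growth rate (ribosomal-protein-like), fall
#' to a low-mu plateau (tRNA-synthetase-like), glucose derepression at
#' low residual glucose, retentostat-specific up- and down-shifts near
#' mu = 0.008 h^-1, a broad stress-like monotone decrease with growth
#' rate, and a near-zero-only dip. Transitions are logistic in log10(mu)
#' with a configurable midpoint (`breakpoint`, h^-1), width (decades)
#' and amplitude.
#'
#' @return list of archetype definitions (`id`, `name`, `shape`,
#'   `breakpoint`, `width`, `amplitude`).
#' @export
default_archetypes <- function() {
  mk <- function(id, name, shape, breakpoint, width, amplitude)
    list(id = id, name = name, shape = shape, breakpoint = breakpoint,
         width = width, amplitude = amplitude)
  list(
    mk(1L, "rising_plateau",   "rise", 0.025, 0.25, 3),
    mk(2L, "falling_plateau",  "fall", 0.005, 0.20, 3),
    mk(3L, "derepressed",      "fall", 0.050, 0.25, 2.5),
    mk(4L, "retentostat_up",   "fall", 0.008, 0.10, 3),
    mk(5L, "stress_down",      "fall", 0.020, 0.50, 2),
    mk(6L, "retentostat_down", "rise", 0.008, 0.10, 3),
    mk(7L, "nearzero_dip",     "dip",  0.0024, 0.18, 0.6))
}

#' Mean profile of an archetype at given growth rates
#'
#' @param archetype one element of [default_archetypes()].
#' @param mu growth rates (h^-1).
#' @return positive relative expression values (around 1).
#' @export
archetype_mean <- function(archetype, mu) {
  x <- log10(mu)
  m <- log10(archetype$breakpoint)
  a <- archetype$amplitude
  w <- archetype$width
  switch(archetype$shape,
         rise = 1 + a * logistic_(x, m, w),
         fall = 1 + a * (1 - logistic_(x, m, w)),
         dip  = 1 - a * exp(-(x - m)^2 / (2 * w^2)),
         stop("unknown archetype shape: ", archetype$shape))
}

#' Generate a synthetic expression matrix with planted structure
#'
#' Responder genes follow an archetype's mean profile evaluated at each
#' sample's growth rate; housekeeping and null genes have constant mean
#' profiles (housekeeping with lower noise). Per-gene baseline
#' intensities are lognormal, the matrix is scaled so that array means
#' are ~300 before noise, and every value is multiplied by lognormal
#' replicate noise at the configured CV. The returned truth table is
#' sufficient to score any downstream stage.
#'
#' @param design sample metadata, default [design_spec()].
#' @param archetypes list from [default_archetypes()].
#' @param n_genes_per_archetype responders per archetype (recycled).
#' @param n_housekeeping constant low-noise genes.
#' @param n_null constant genes at replicate noise.
#' @param noise a [noise_spec()].
#' @return list `matrix` (genes x samples), `metadata` (the design),
#'   `truth` (`gene_id`, `class`, `archetype`, `responder`).
#' @export
generate_expression <- function(design = design_spec(),
                                archetypes = default_archetypes(),
                                n_genes_per_archetype = 100,
                                n_housekeeping = 50, n_null = 500,
                                noise = noise_spec()) {
  n_arch <- rep_len(n_genes_per_archetype, length(archetypes))
  total <- sum(n_arch) + n_housekeeping + n_null
  if (total == 0) stop("no genes requested")
  set.seed(noise$seed)
  mu <- design$growth_rate
  rows <- vector("list", length(archetypes))
  truth <- vector("list", length(archetypes))
  for (i in seq_along(archetypes)) {
    a <- archetypes[[i]]
    if (n_arch[i] == 0) { rows[[i]] <- NULL; next }
    ids <- sprintf("A%d_g%03d", a$id, seq_len(n_arch[i]))
    shape <- archetype_mean(a, mu)
    base <- stats::rlnorm(n_arch[i], log(150), 0.6)
    rows[[i]] <- outer(base, shape)
    rownames(rows[[i]]) <- ids
    truth[[i]] <- data.frame(gene_id = ids, class = a$name,
                             archetype = a$id, responder = TRUE,
                             stringsAsFactors = FALSE)
  }
  extra <- function(prefix, n, cls) {
    if (n == 0) return(NULL)
    ids <- sprintf("%s_g%03d", prefix, seq_len(n))
    m <- matrix(stats::rlnorm(n, log(150), 0.6), n, length(mu))
    rownames(m) <- ids
    list(m = m, truth = data.frame(gene_id = ids, class = cls,
                                   archetype = NA_integer_,
                                   responder = FALSE,
                                   stringsAsFactors = FALSE))
  }
  hk <- extra("HK", n_housekeeping, "housekeeping")
  nul <- extra("NULL", n_null, "null")
  mean_mat <- do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)],
                               list(hk$m, nul$m)))
  truth <- do.call(rbind, c(truth[!vapply(truth, is.null, TRUE)],
                            list(hk$truth, nul$truth)))
  colnames(mean_mat) <- design$sample_id
  mean_mat <- mean_mat * 300 / mean(colMeans(mean_mat))
  cv <- ifelse(truth$class == "housekeeping",
               noise$housekeeping_cv, noise$replicate_cv)
  sdlog <- sqrt(log(1 + cv^2))
  noise_mat <- matrix(stats::rnorm(length(mean_mat)), nrow(mean_mat))
  noise_mat <- exp(noise_mat * sdlog - sdlog^2 / 2)  # unit-mean lognormal
  mat <- mean_mat * noise_mat
  list(matrix = mat, metadata = design, truth = truth)
}

#' Generate a retentostat biomass/viability time series
#'
#' Viable biomass follows the ideal maintenance-energy trajectory
#' ([predict_biomass()]); viability decays as
#' v(t) = v_inf + (1 - v_inf) exp(-lambda t); the measured total biomass
#' is viable biomass divided by viability, with multiplicative lognormal
#' measurement noise. The exact specific growth rate
#' mu(t) = (dCx_total/dt) / Cx_viable is recorded for recovery studies.
#'
#' @param params a [retentostat_params()] object.
#' @param duration_d run length in days (default 22).
#' @param sampling_times sampling grid (h); default every 48 h.
#' @param noise_cv CV of biomass measurement noise (default 0.02).
#' @param v_inf asymptotic viable fraction in (0, 1].
#' @param lambda viability decay rate (h^-1), >= 0.
#' @param seed RNG seed.
#' @return list `series` (a [biomass_series()] of noisy measurements)
#'   and `truth` (`time_h`, `cx_viable`, `cx_total`, `viability`, `mu`).
#' @export
generate_retentostat_series <- function(params = retentostat_params(),
                                        duration_d = 22,
                                        sampling_times = seq(0, duration_d * 24, by = 48),
                                        noise_cv = 0.02,
                                        v_inf = 0.8, lambda = 0.005,
                                        seed = 1) {
  stopifnot(inherits(params, "retentostat_params"))
  if (lambda < 0) stop("lambda must be >= 0")
  if (v_inf <= 0 || v_inf > 1) stop("v_inf must lie in (0, 1]")
  t <- sampling_times
  cx_v <- predict_biomass(params, t)
  v <- v_inf + (1 - v_inf) * exp(-lambda * t)
  cx_tot <- cx_v / v
  k <- params$ms_g * params$Ysx_max
  cx_inf <- params$D * (params$Cs_in - params$Cs) / params$ms_g
  dcx_v <- k * (cx_inf - cx_v)
  dv <- -lambda * (1 - v_inf) * exp(-lambda * t)
  dcx_tot <- (dcx_v * v - cx_v * dv) / v^2
  mu_true <- dcx_tot / cx_v
  set.seed(seed)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    cx_obs <- cx_tot * exp(stats::rnorm(length(t)) * sdlog - sdlog^2 / 2)
  } else cx_obs <- cx_tot
  list(series = biomass_series(t, cx_obs, v),
       truth = data.frame(time_h = t, cx_viable = cx_v, cx_total = cx_tot,
                          viability = v, mu = mu_true))
}

#' Generate annotation gene sets with planted enrichment
#'
#' Planted sets draw their members preferentially (at the given odds)
#' from genes of a target truth class; decoy sets draw uniformly from
#' the whole universe. Sets requested with size zero are dropped with a
#' warning.
#'
#' @param truth truth table from [generate_expression()].
#' @param planted data.frame with `set_name`, `class` (a truth class to
#'   enrich for) and `odds` (weight of target-class genes relative to
#'   the rest, e.g. 8).
#' @param n_decoys number of uniformly drawn decoy sets.
#' @param set_size members per set (recycled over planted then decoys).
#' @param seed RNG seed.
#' @return list `collection` (a [gene_set_collection()] over all
#'   generated genes) and `planted` (the planted design).
#' @export
generate_gene_sets <- function(truth, planted = NULL, n_decoys = 10,
                               set_size = 100, seed = 1) {
  universe <- truth$gene_id
  n_planted <- if (is.null(planted)) 0 else nrow(planted)
  sizes <- rep_len(set_size, n_planted + n_decoys)
  if (any(sizes > length(universe)))
    stop("requested set size exceeds the universe")
  set.seed(seed)
  sets <- list()
  if (n_planted) for (i in seq_len(n_planted)) {
    if (sizes[i] == 0) { warning("dropping zero-size set request"); next }
    if (!planted$class[i] %in% truth$class)
      stop("planted class not present in truth: ", planted$class[i])
    w <- ifelse(truth$class == planted$class[i], planted$odds[i], 1)
    sets[[planted$set_name[i]]] <-
      sample(universe, sizes[i], prob = w / sum(w))
  }
  for (j in seq_len(n_decoys)) {
    sz <- sizes[n_planted + j]
    if (sz == 0) { warning("dropping zero-size set request"); next }
    sets[[sprintf("decoy_%02d", j)]] <- sample(universe, sz)
  }
  list(collection = gene_set_collection(sets, universe), planted = planted)
}

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Generate promoter sequences with a planted motif
#'
#' Promoters are i.i.d. bases at the given GC content. `p_planted`
#' (genes in `planted_genes`) and `p_background` (all others) are
#' target motif *hit rates* under the standard both-strand scan: since
#' random backgrounds already contain spontaneous matches, the stamping
#' probability is calibrated against the realized spontaneous hit
#' fraction (q = (p - s)/(1 - s)) so that the expected final hit
#' fraction of each group equals its target. A stamp inserts one
#' concrete instance of the IUPAC motif — degenerate positions expanded
#' at random, random strand, random offset. Spontaneous matches are
#' never removed, so hits remain possible even at a target of zero.
#'
#' @param gene_ids promoter ids.
#' @param length promoter length in bp upstream (default 800).
#' @param gc GC content (default 0.38, yeast-like).
#' @param motif IUPAC motif to plant.
#' @param p_background target hit rate outside `planted_genes`.
#' @param p_planted target hit rate for `planted_genes`.
#' @param planted_genes ids of the enriched group.
#' @param seed RNG seed.
#' @return a named `Biostrings::DNAStringSet`.
#' @export
generate_promoters <- function(gene_ids, length = 800, gc = 0.38,
                               motif = "TCGTTYAG", p_background = 0.1,
                               p_planted = 0.4,
                               planted_genes = character(), seed = 1) {
  if (p_background < 0 || p_planted > 1 || p_background > p_planted)
    stop("need 0 <= p_background <= p_planted <= 1")
  chars <- strsplit(toupper(motif), "")[[1]]
  if (!all(chars %in% names(IUPAC_EXPANSION)))
    stop("invalid IUPAC character in motif")
  if (nchar(motif) > length) stop("motif longer than the promoter")
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  backgrounds <- vapply(gene_ids, function(g)
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  # realized spontaneous hit fraction, used to calibrate stamping
  s_hat <- mean(scan_motif(backgrounds, motif)$hit)
  stamp_prob <- function(p) min(1, max(0, (p - s_hat) / (1 - s_hat)))
  q_planted <- stamp_prob(p_planted)
  q_background <- stamp_prob(p_background)
  revcomp_ <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                             "")[[1]]), collapse = "")
  seqs <- vapply(gene_ids, function(g) {
    s <- backgrounds[[g]]
    q <- if (g %in% planted_genes) q_planted else q_background
    if (stats::runif(1) < q) {
      inst <- paste(vapply(chars, function(ch)
        sample(IUPAC_EXPANSION[[ch]], 1), character(1)), collapse = "")
      if (stats::runif(1) < 0.5) inst <- revcomp_(inst)
      off <- sample.int(length - nchar(inst) + 1, 1)
      substr(s, off, off + nchar(inst) - 1) <- inst
    }
    s
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, gene_ids))
}
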