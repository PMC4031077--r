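# Synthetic study generator with planted truth. One scenario seed drives
# named substreams (panel layout, chromatin, array design, per-sample
# assay noise), so adding a generator never perturbs the outputs of the
# existing ones. Truth is defined on the IMS-like linear signal scale
# (alpha = 1); percent-scale truth is a logistic squash of the same signal
# so the mDIP and bisulfite assays are driven from one truth table.

#' Simulation scenario
#'
#' Defines the synthetic study conditions: an island panel in which a
#' configurable majority of islands are unmethylated in every tissue
#' sample, ES-like test samples with a planted subset of aberrantly
#' methylated islands, Tm-dependent probe signal bias, Poisson read depth
#' with binomial methylated-read sampling, and an optional linear coupling
#' between H3K27me3 density and the planted methylation gain, attenuated
#' by H3K4me3.
#'
#' @param seed Integer scenario seed; every generator consumes only
#'   substreams derived from it.
#' @param n_islands Number of CpG islands (default 2000).
#' @param n_background_probes Array probes outside any island
#'   (default 2000); they carry the methylated-compartment signal so
#'   islands stand out as low.
#' @param probes_per_island,cpgs_per_island Integer ranges `c(lo, hi)`.
#' @param n_tissue_samples,n_test_samples Panel sizes (defaults 6 and 3).
#' @param frac_constitutive Fraction of islands truly unmethylated in all
#'   tissues (default 0.9).
#' @param n_planted_aberrant Islands from the constitutive pool given a
#'   methylation gain in test samples (default 30).
#' @param planted_effect True methylation gain on the IMS signal scale
#'   when no chromatin coupling is active (default 1.2).
#' @param methylated_level IMS-scale signal of the methylated compartment
#'   (non-constitutive islands and non-island background, default 2).
#' @param tm_mean,tm_sd Probe melting-temperature distribution in degrees
#'   Celsius (defaults 77 and 4).
#' @param tm_bias `"linear"` (default) or `"quadratic"` Tm bias shape.
#' @param tm_bias_coef Bias coefficient: log2-ratio units per degree C
#'   (linear) or per squared degree (quadratic); default 0.1.
#' @param noise_sd Per-probe assay noise sd in log2-ratio units
#'   (default 0.25).
#' @param read_depth_mean Poisson mean read depth per CpG (default 30).
#' @param k27_coupling Slope of the planted gain per unit of normalized
#'   H3K27me3 density; 0 (default) plants a uniform `planted_effect` gain.
#' @param k4_protection Attenuation of the coupled gain per unit of
#'   normalized H3K4me3 density (default 0).
#' @param coupling_noise_sd Noise sd on the coupled gain (default 0.05).
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(seed = 17L, n_islands = 2000L,
                                n_background_probes = 2000L,
                                probes_per_island = c(6L, 12L),
                                cpgs_per_island = c(5L, 15L),
                                n_tissue_samples = 6L,
                                n_test_samples = 3L,
                                frac_constitutive = 0.9,
                                n_planted_aberrant = 30L,
                                planted_effect = 1.2,
                                methylated_level = 2,
                                tm_mean = 77, tm_sd = 4,
                                tm_bias = c("linear", "quadratic"),
                                tm_bias_coef = 0.1,
                                noise_sd = 0.25,
                                read_depth_mean = 30,
                                k27_coupling = 0, k4_protection = 0,
                                coupling_noise_sd = 0.05) {
  tm_bias <- match.arg(tm_bias)
  sc <- list(seed = as.integer(seed), n_islands = as.integer(n_islands),
             n_background_probes = as.integer(n_background_probes),
             probes_per_island = as.integer(probes_per_island),
             cpgs_per_island = as.integer(cpgs_per_island),
             n_tissue_samples = as.integer(n_tissue_samples),
             n_test_samples = as.integer(n_test_samples),
             frac_constitutive = frac_constitutive,
             n_planted_aberrant = as.integer(n_planted_aberrant),
             planted_effect = planted_effect,
             methylated_level = methylated_level,
             tm_mean = tm_mean, tm_sd = tm_sd, tm_bias = tm_bias,
             tm_bias_coef = tm_bias_coef, noise_sd = noise_sd,
             read_depth_mean = read_depth_mean,
             k27_coupling = k27_coupling, k4_protection = k4_protection,
             coupling_noise_sd = coupling_noise_sd)
  n_const <- floor(sc$frac_constitutive * sc$n_islands)
  if (sc$n_planted_aberrant > n_const)
    stop("infeasible scenario: n_planted_aberrant exceeds the ",
         "constitutive pool (", n_const, ")", call. = FALSE)
  stopifnot(sc$n_islands >= 1, sc$frac_constitutive >= 0,
            sc$frac_constitutive <= 1,
            length(sc$probes_per_island) == 2,
            length(sc$cpgs_per_island) == 2,
            sc$noise_sd >= 0, sc$read_depth_mean >= 0)
  structure(sc, class = "simulation_scenario")
}

#' Write / read a scenario as a flat YAML config
#'
#' @param scenario A [simulation_scenario()].
#' @param path File path.
#' @return `path` invisibly ([write_scenario()]); the scenario
#'   ([read_scenario()]).
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  do.call(simulation_scenario, yaml::read_yaml(path))
}

# Deterministic named substreams off the scenario seed; kept below 2^31.
substream_seed <- function(seed, stream, index = 0L) {
  offsets <- c(panel = 101L, chromatin = 223L, design = 337L,
               mdip = 449L, rrbs = 557L)
  off <- offsets[[stream]]
  ((as.numeric(seed) %% 100003) * 13591 + off * 7919 + index * 104729) %%
    2147483629
}

squash_percent <- function(ims_signal) {
  100 * stats::plogis(4 * (ims_signal - 1))
}

sample_names <- function(scenario) {
  list(tissue = sprintf("tissue%02d", seq_len(scenario$n_tissue_samples)),
       test = sprintf("es%02d", seq_len(scenario$n_test_samples)))
}

#' Simulate the island panel and truth table
#'
#' Lays out non-overlapping islands on a synthetic chromosome, draws the
#' constitutive (truly unmethylated-in-tissue) pool and plants the
#' aberrant subset inside it. Truth is recorded on the IMS signal scale
#' (`ims_tissue`, `ims_gain`) and as squashed percent values.
#'
#' @param scenario A [simulation_scenario()].
#' @return List with `islands` (validated island data.frame) and `truth`
#'   (per-island truth table).
#' @export
simulate_panel <- function(scenario) {
  set.seed(substream_seed(scenario$seed, "panel"))
  n <- scenario$n_islands
  widths <- sample(500:2000, n, replace = TRUE)
  gaps <- sample(5000:15000, n, replace = TRUE)
  starts <- cumsum(gaps) + cumsum(c(0L, widths[-n]))
  islands <- data.frame(chrom = "chrS", start = starts,
                        end = starts + widths,
                        island_id = sprintf("isl%05d", seq_len(n)),
                        stringsAsFactors = FALSE)
  islands$n_probes_planned <- sample(
    scenario$probes_per_island[1]:scenario$probes_per_island[2], n,
    replace = TRUE)
  islands$n_cpgs_planned <- sample(
    scenario$cpgs_per_island[1]:scenario$cpgs_per_island[2], n,
    replace = TRUE)
  n_const <- floor(scenario$frac_constitutive * n)
  const_idx <- sort(sample(n, n_const))
  planted_idx <- sort(sample(const_idx,
                             scenario$n_planted_aberrant))
  truth <- data.frame(island_id = islands$island_id,
                      constitutive = seq_len(n) %in% const_idx,
                      planted_aberrant = seq_len(n) %in% planted_idx,
                      stringsAsFactors = FALSE)
  truth$ims_tissue <- ifelse(truth$constitutive, 0,
                             scenario$methylated_level)
  truth$ims_gain <- ifelse(truth$planted_aberrant,
                           scenario$planted_effect, 0)
  truth$ims_test <- truth$ims_tissue + truth$ims_gain
  truth$percent_tissue <- squash_percent(truth$ims_tissue)
  truth$percent_test <- squash_percent(truth$ims_test)
  truth$percent_tissue[truth$ims_tissue == 0] <- 0
  truth$percent_test[truth$ims_test == 0] <- 0
  list(islands = validate_islands(islands), truth = truth)
}

#' Simulate per-island chromatin densities and couple the planted gain
#'
#' Draws H3K27me3 and H3K4me3 raw densities (planted islands are drawn
#' from a higher-H3K27me3 distribution, emulating polycomb targeting).
#' When `k27_coupling > 0` the planted methylation gain is overwritten by
#' `k27_coupling * k27_norm * max(0, 1 - k4_protection * k4_norm)` plus
#' noise, and the truth table is updated accordingly.
#'
#' @param panel Output of [simulate_panel()].
#' @param scenario A [simulation_scenario()].
#' @return `panel` with an added `density` long data.frame (`island_id`,
#'   `mark`, `raw_score`) and the truth table extended with
#'   `k27_raw`/`k27_norm`/`k4_raw`/`k4_norm` (and updated gains).
#' @export
simulate_chromatin <- function(panel, scenario) {
  truth <- panel$truth
  set.seed(substream_seed(scenario$seed, "chromatin"))
  n <- nrow(truth)
  k27 <- numeric(n); k4 <- numeric(n)
  planted <- truth$planted_aberrant
  const <- truth$constitutive
  k27[planted] <- stats::rgamma(sum(planted), shape = 6, scale = 2)
  k27[const & !planted] <- stats::rgamma(sum(const & !planted),
                                         shape = 1.2, scale = 2)
  k27[!const] <- stats::rgamma(sum(!const), shape = 3, scale = 2)
  k4[const] <- stats::rgamma(sum(const), shape = 4, scale = 2)
  k4[!const] <- stats::rgamma(sum(!const), shape = 1, scale = 1)
  truth$k27_raw <- k27
  truth$k27_norm <- k27 / mean(k27)
  truth$k4_raw <- k4
  truth$k4_norm <- k4 / mean(k4)
  if (scenario$k27_coupling > 0) {
    gain <- scenario$k27_coupling * truth$k27_norm[planted] *
      pmax(0, 1 - scenario$k4_protection * truth$k4_norm[planted]) +
      stats::rnorm(sum(planted), 0, scenario$coupling_noise_sd)
    truth$ims_gain[planted] <- pmax(0, gain)
    truth$ims_test <- truth$ims_tissue + truth$ims_gain
    truth$percent_test <- squash_percent(truth$ims_test)
    truth$percent_test[truth$ims_test == 0] <- 0
  }
  panel$truth <- truth
  panel$density <- data.frame(
    island_id = rep(truth$island_id, 2),
    mark = rep(c("H3K27me3", "H3K4me3"), each = n),
    raw_score = c(truth$k27_raw, truth$k4_raw),
    stringsAsFactors = FALSE)
  panel
}

# Fixed array design shared by all samples of a scenario: probe
# positions, Tm draws and island membership.
simulate_probe_design <- function(panel, scenario) {
  set.seed(substream_seed(scenario$seed, "design"))
  islands <- panel$islands
  per <- islands$n_probes_planned
  idx <- rep(seq_len(nrow(islands)), per)
  offs <- unlist(lapply(seq_len(nrow(islands)), function(i) {
    w <- islands$end[i] - islands$start[i]
    sort(sample(0:(w - 50L), per[i], replace = FALSE))
  }))
  island_probes <- data.frame(
    probe_id = sprintf("p_isl%06d", seq_along(idx)),
    chrom = "chrS",
    start = islands$start[idx] + offs,
    end = pmin(islands$start[idx] + offs + 50L, islands$end[idx]),
    island_id = islands$island_id[idx], stringsAsFactors = FALSE)
  nbg <- scenario$n_background_probes
  bg_start <- max(islands$end) + 10000L + seq_len(nbg) * 100L
  bg_probes <- data.frame(probe_id = sprintf("p_bg%06d", seq_len(nbg)),
                          chrom = "chrS", start = bg_start,
                          end = bg_start + 50L,
                          island_id = BACKGROUND_KEY,
                          stringsAsFactors = FALSE)
  design <- rbind(island_probes, bg_probes)
  design$tm <- stats::rnorm(nrow(design), scenario$tm_mean,
                            scenario$tm_sd)
  design
}

tm_bias_fun <- function(scenario) {
  coef <- scenario$tm_bias_coef
  mu <- scenario$tm_mean
  if (scenario$tm_bias == "linear") function(tm) coef * (tm - mu)
  else function(tm) coef * (tm - mu)^2
}

#' Simulate mDIP probe intensity tables
#'
#' The per-probe log-ratio signal is
#' `truth + tm_bias(Tm) + N(0, noise_sd)`, where truth is the island's
#' IMS-scale methylation for the sample's role and non-island background
#' probes carry the methylated-compartment level. Intensities are
#' back-computed (`bound = input * 2^signal` around a lognormal input
#' channel) so that [compute_log_ratios()] recovers the signal up to a
#' constant shift. The probe design (positions, Tm) is fixed across
#' samples; only the assay noise differs.
#'
#' @param panel Output of [simulate_panel()] (or [simulate_chromatin()]).
#' @param scenario A [simulation_scenario()].
#' @return List with `probes` (named list of per-sample probe tables),
#'   `design`, and `roles`.
#' @export
simulate_mdip <- function(panel, scenario) {
  design <- simulate_probe_design(panel, scenario)
  truth <- panel$truth
  bias <- tm_bias_fun(scenario)(design$tm)
  nm <- sample_names(scenario)
  tix <- match(design$island_id, truth$island_id)
  base_tissue <- ifelse(is.na(tix), scenario$methylated_level,
                        truth$ims_tissue[tix])
  base_test <- ifelse(is.na(tix), scenario$methylated_level,
                      truth$ims_test[tix])
  all_samples <- c(nm$tissue, nm$test)
  roles <- sample_roles(all_samples,
                        rep(c("tissue", "es_test"),
                            c(length(nm$tissue), length(nm$test))),
                        "mdip")
  probes <- vector("list", length(all_samples))
  names(probes) <- all_samples
  for (i in seq_along(all_samples)) {
    set.seed(substream_seed(scenario$seed, "mdip", i))
    signal_base <- if (all_samples[i] %in% nm$tissue) base_tissue else
      base_test
    signal <- signal_base + bias +
      stats::rnorm(nrow(design), 0, scenario$noise_sd)
    input <- exp(stats::rnorm(nrow(design), log(1000), 0.3))
    probes[[i]] <- data.frame(probe_id = design$probe_id,
                              chrom = design$chrom,
                              start = design$start, end = design$end,
                              tm = design$tm, bound = input * 2^signal,
                              input = input, stringsAsFactors = FALSE)
  }
  list(probes = probes, design = design, roles = roles)
}

#' Simulate RRBS per-CpG count tables
#'
#' CpG positions are evenly spaced within each island; per CpG the read
#' depth is Poisson(`read_depth_mean`) and methylated reads are
#' Binomial(depth, true island percent / 100). CpGs drawing depth 0 are
#' omitted from the emitted table (they were never observed), but the
#' planned CpG count is reported so exclusion rates can be computed
#' against the closed-form Poisson tail.
#'
#' @param panel Output of [simulate_panel()] (or later stages).
#' @param scenario A [simulation_scenario()].
#' @param samples Which samples to emit: `"tissue"`, `"test"`, or both
#'   (default both).
#' @return List with `counts` (named list of per-sample CpG count
#'   data.frames), `roles`, and `n_cpgs_planned` (per sample, before the
#'   depth-0 drop).
#' @export
simulate_rrbs <- function(panel, scenario,
                          samples = c("tissue", "test")) {
  samples <- match.arg(samples, several.ok = TRUE)
  islands <- panel$islands
  truth <- panel$truth
  per <- islands$n_cpgs_planned
  pos_list <- lapply(seq_len(nrow(islands)), function(i) {
    w <- islands$end[i] - islands$start[i]
    islands$start[i] + unique(round(seq(5, w - 5, length.out = per[i])))
  })
  pos <- unlist(pos_list)
  idx <- rep(seq_len(nrow(islands)), lengths(pos_list))
  nm <- sample_names(scenario)
  want <- c(if ("tissue" %in% samples) nm$tissue,
            if ("test" %in% samples) nm$test)
  roles <- sample_roles(want,
                        ifelse(want %in% nm$tissue, "tissue", "es_test"),
                        "rrbs")
  p_tissue <- truth$percent_tissue[idx] / 100
  p_test <- truth$percent_test[idx] / 100
  counts <- vector("list", length(want))
  names(counts) <- want
  for (i in seq_along(want)) {
    sample_index <- match(want[i], c(nm$tissue, nm$test))
    set.seed(substream_seed(scenario$seed, "rrbs", sample_index))
    depth <- stats::rpois(length(pos), scenario$read_depth_mean)
    p <- if (want[i] %in% nm$tissue) p_tissue else p_test
    meth <- stats::rbinom(length(pos), depth, p)
    keep <- depth > 0
    counts[[i]] <- data.frame(chrom = "chrS", pos = pos[keep],
                              meth = meth[keep], total = depth[keep],
                              stringsAsFactors = FALSE)
  }
  list(counts = counts, roles = roles, n_cpgs_planned = length(pos))
}

#' Simulate a full study
#'
#' Runs panel layout, chromatin density generation, mDIP probe simulation
#' and RRBS count simulation from one scenario seed.
#'
#' @param scenario A [simulation_scenario()].
#' @param assays Which assays to simulate (default both).
#' @return List with `scenario`, `islands`, `truth`, `density`, `mdip`,
#'   `rrbs`.
#' @export
simulate_study <- function(scenario = simulation_scenario(),
                           assays = c("mdip", "rrbs")) {
  assays <- match.arg(assays, several.ok = TRUE)
  panel <- simulate_chromatin(simulate_panel(scenario), scenario)
  out <- list(scenario = scenario, islands = panel$islands,
              truth = panel$truth, density = panel$density)
  if ("mdip" %in% assays) out$mdip <- simulate_mdip(panel, scenario)
  if ("rrbs" %in% assays) out$rrbs <- simulate_rrbs(panel, scenario)
  out
}
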