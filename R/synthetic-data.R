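#' Simulation configuration for a synthetic contact zone
#'
#' Bundles the ground-truth parameters of the synthetic transect: two species
#' meeting at a sharp contact on a ~14.58 km transect, species-specific
#' landmark mean shapes and covariance structures with a controllable angle
#' between leading eigenvectors, sigmoid clines of known center and width,
#' rare F1 hybrids (and no backcrosses), and smooth environmental gradients
#' whose centers are offset west of the species transition.
#'
#' @param n_individuals Number of specimens on the transect.
#' @param transect_length_km Transect length (default 14.58 km).
#' @param contact_km Position of the species transition (default 9.0 km).
#' @param cline_width_km Generating cline width (default 0.125 km).
#' @param n_wing_landmarks,n_genital_landmarks Landmark counts (23 and 11).
#' @param pmax_angle_deg True angle between the species' leading eigenvectors
#'   in shape space (default 45).
#' @param eigen_spectrum Decreasing positive leading eigenvalues of the
#'   within-species shape covariance (unitless multipliers of `var_unit`);
#'   remaining shape dimensions get `min(eigen_spectrum)/4`.
#' @param var_unit Variance of one spectrum unit, in squared Procrustes
#'   units (default 1e-5, i.e. SD 0.01 Procrustes units along a unit-10 axis).
#' @param shape_divergence Between-species mean-shape offset in Procrustes
#'   units (default 0.02, about six within-species SDs along the offset axis:
#'   enough for near-perfect discriminant assignment while keeping the
#'   leading PC's variance fraction at a realistic level).
#' @param f1_rate Expected F1 fraction (default 3/464, matching a handful of
#'   F1s in several hundred specimens).
#' @param genotyped_fraction Fraction of specimens with genotypes.
#' @param n_diagnostic_snps,n_background_snps SNP counts (defaults 60 / 240).
#' @param env_cline_center_km Center of the environmental gradients (default
#'   3.0 km, west of the contact).
#' @param env_noise_sd Environmental noise SD (standardized units).
#' @param hard_split If `TRUE`, species are split deterministically at the
#'   contact instead of drawn from the sigmoid.
#' @param spot_landmarks Wing-landmark subset delimiting the orange spot
#'   (configuration input; default 10:16).
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 464L,
                              transect_length_km = 14.58,
                              contact_km = 9.0,
                              cline_width_km = 0.125,
                              n_wing_landmarks = 23L,
                              n_genital_landmarks = 11L,
                              pmax_angle_deg = 45,
                              eigen_spectrum = c(10, 2, 1, 0.5, 0.25, 0.125),
                              var_unit = 1e-5,
                              shape_divergence = 0.02,
                              f1_rate = 3 / 464,
                              genotyped_fraction = 0.4,
                              n_diagnostic_snps = 60L,
                              n_background_snps = 240L,
                              env_cline_center_km = 3.0,
                              env_noise_sd = 1.0,
                              hard_split = FALSE,
                              spot_landmarks = 10:16,
                              seed = 1L) {
  if (contact_km <= 0 || contact_km >= transect_length_km)
    stop("contact_km must lie inside (0, transect_length_km)")
  if (any(diff(eigen_spectrum) > 0))
    stop("eigen_spectrum must be non-increasing")
  if (f1_rate < 0 || f1_rate >= 1) stop("f1_rate must be in [0, 1)")
  if (pmax_angle_deg < 0 || pmax_angle_deg > 90)
    stop("pmax_angle_deg must be in [0, 90]")
  structure(as.list(environment()), class = "simulation_config")
}

#' Paper-scale preset configuration
#'
#' The default study-scale conditions: 464 contact-zone specimens, 23 wing
#' and 11 genital landmarks, 300 SNPs (60 diagnostic + 240 background),
#' a 14.58 km transect with the contact at 9.0 km, and an F1 rate giving
#' about 3 expected F1 hybrids.
#'
#' @param seed Integer seed.
#' @return A `simulation_config`.
#' @export
paper_scale_preset <- function(seed = 1L) {
  simulation_config(n_individuals = 464L, n_diagnostic_snps = 60L,
                    n_background_snps = 240L, f1_rate = 3 / 464, seed = seed)
}

# Stylized wing outline: 23 landmarks on a smooth asymmetric oval with a
# notch, roughly where venation landmarks would sit. Unit scale.
wing_template <- function() {
  t <- seq(0, 2 * pi, length.out = 24)[-24]
  r <- 1 + 0.3 * cos(t) + 0.15 * sin(2 * t) + 0.05 * cos(3 * t)
  cbind(x = 1.4 * r * cos(t), y = 0.8 * r * sin(t))
}

# Stylized genital valve outline: 11 landmarks.
genital_template <- function() {
  t <- seq(0, 2 * pi, length.out = 12)[-12]
  r <- 1 + 0.25 * cos(2 * t) + 0.1 * sin(3 * t)
  cbind(x = r * cos(t), y = 0.5 * r * sin(t))
}

# Orthonormal basis of the shape tangent space at a template: the
# orthogonal complement (2k-4 columns) of translations, scaling and rotation.
shape_tangent_basis <- function(template) {
  k <- nrow(template)
  Tc <- sweep(template, 2, colMeans(template))
  S <- cbind(c(rep(1, k), rep(0, k)),
             c(rep(0, k), rep(1, k)),
             as.vector(Tc),
             as.vector(cbind(-Tc[, 2], Tc[, 1])))
  Q <- qr.Q(qr(S), complete = TRUE)
  Q[, 5:(2 * k), drop = FALSE]
}

givens <- function(m, angle_deg) {
  G <- diag(m)
  a <- angle_deg * pi / 180
  G[1, 1] <- cos(a); G[2, 2] <- cos(a)
  G[1, 2] <- -sin(a); G[2, 1] <- sin(a)
  G
}

#' Simulate two populations with a known angle between leading eigenvectors
#'
#' Draws multivariate-normal samples from two covariance matrices that share
#' the same eigenvalue spectrum but whose leading eigenvectors are separated
#' by exactly `pmax_angle_deg` (the eigenbasis of the second population is
#' rotated in the plane of the first two axes). Used to validate theta
#' estimation and the bootstrap comparison with known ground truth.
#'
#' @param n_per_pop Sample size per population.
#' @param pmax_angle_deg True angle in degrees, in \[0, 90\].
#' @param eigen_spectrum Decreasing positive eigenvalues (trait dimension =
#'   its length).
#' @param seed Integer seed.
#' @return List with `XA`, `XB` (samples), `pmax_A`, `pmax_B` (true leading
#'   eigenvectors), `cov_A`, `cov_B`.
#' @export
simulate_two_populations <- function(n_per_pop, pmax_angle_deg,
                                     eigen_spectrum = c(10, 2, 1, 0.5, 0.25),
                                     seed = 1L) {
  if (pmax_angle_deg < 0 || pmax_angle_deg > 90)
    stop("pmax_angle_deg must be in [0, 90]")
  d <- length(eigen_spectrum)
  if (d < 2L) stop("need at least 2 traits")
  set.seed(as.integer(seed))
  G <- givens(d, pmax_angle_deg)
  covA <- diag(eigen_spectrum)
  covB <- G %*% covA %*% t(G)
  XA <- MASS::mvrnorm(n_per_pop, mu = rep(0, d), Sigma = covA)
  XB <- MASS::mvrnorm(n_per_pop, mu = rep(0, d), Sigma = covB)
  list(XA = XA, XB = XB, pmax_A = c(1, rep(0, d - 1)), pmax_B = G[, 1],
       cov_A = covA, cov_B = covB)
}

sample_shapes <- function(template, n, species, cfg, u_offset_dim = 3L) {
  k <- nrow(template)
  U <- shape_tangent_basis(template)
  m <- ncol(U)
  spec <- cfg$eigen_spectrum
  if (length(spec) > m) spec <- spec[seq_len(m)]
  vars <- c(spec, rep(min(spec) / 4, m - length(spec))) * cfg$var_unit
  G <- givens(m, cfg$pmax_angle_deg)
  offset <- numeric(m)
  offset[min(u_offset_dim, m)] <- cfg$shape_divergence / 2
  Z <- matrix(stats::rnorm(n * m), n, m)
  dev <- matrix(0, n, m)
  for (i in seq_len(n)) {
    zi <- Z[i, ] * sqrt(vars)
    dev[i, ] <- switch(species[i],
      A = zi - offset,
      B = drop(G %*% zi) + offset,
      hybrid = zi)  # parental midpoint mean, unrotated noise
  }
  confs <- dev %*% t(U)   # n x 2k deviations in landmark space
  list(confs = confs, U = U,
       pmax_A = U %*% c(1, rep(0, m - 1)),
       pmax_B = U %*% G[, 1])
}

#' Simulate a complete synthetic contact-zone dataset
#'
#' Generates everything the pipeline consumes, with known ground truth:
#' specimen positions uniform on the transect; species labels drawn from the
#' true sigmoid at each position (or split deterministically with
#' `hard_split`); wing and genital landmark configurations built around fixed
#' template outlines, with species mean shapes offset by `shape_divergence`
#' and within-species covariance whose leading eigenvectors differ by
#' `pmax_angle_deg` between species; F1 hybrids at rate `f1_rate` placed
#' within 0.25 km of the contact, heterozygous at every diagnostic SNP and
#' with landmark means at the parental midpoint; genotypes with diagnostic
#' sites fixed between species plus background sites at shared Beta(2,2)
#' frequencies; and environmental variables following logistic gradients
#' centered at `env_cline_center_km` (west of the contact) plus Gaussian
#' noise.
#'
#' @param cfg A [simulation_config].
#' @return A list of class `transect_simulation` with `specimens`
#'   (data.frame), `wings`, `genitalia` (lists of [landmark_set]),
#'   `genotypes` ([genotype_matrix] of the genotyped subset), `env`
#'   (data.frame), and `truth` (all generating parameters, true leading
#'   eigenvectors, hybrid ids, environmental centers).
#' @export
simulate_transect <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(as.integer(cfg$seed))
  n <- cfg$n_individuals
  L <- cfg$transect_length_km
  x <- stats::runif(n, 0, L)
  pB <- sigmoid_mean(x, cfg$contact_km, cfg$cline_width_km, 0, 1)
  species <- if (cfg$hard_split) ifelse(x > cfg$contact_km, "B", "A")
             else ifelse(stats::rbinom(n, 1, pB) == 1, "B", "A")
  # F1 hybrids near the contact
  n_f1 <- stats::rbinom(1, n, cfg$f1_rate)
  f1_idx <- integer(0)
  if (n_f1 > 0) {
    f1_idx <- sample.int(n, n_f1)
    # F1s arise where both parental species fly: within the sigmoid mixing
    # zone (half a cline width of the contact), capped at 0.25 km
    f1_spread <- min(0.25, cfg$cline_width_km / 2)
    x[f1_idx] <- cfg$contact_km + stats::runif(n_f1, -f1_spread, f1_spread)
    species[f1_idx] <- "hybrid"
  }
  ids <- sprintf("spec_%03d", seq_len(n))

  wings_dev <- sample_shapes(wing_template(), n, species, cfg)
  gen_dev <- sample_shapes(genital_template(), n, species, cfg)
  sizes <- 300 * exp(stats::rnorm(n, 0, 0.03))   # image units (pixels)
  build_sets <- function(template, dev, scale_by_size) {
    k <- nrow(template)
    lapply(seq_len(n), function(i) {
      co <- template + matrix(dev$confs[i, ], k, 2)
      if (scale_by_size) co <- co * sizes[i]
      landmark_set(ids[i], co)
    })
  }
  wings <- build_sets(wing_template(), wings_dev, TRUE)
  genitalia <- build_sets(genital_template(), gen_dev, FALSE)
  wl <- vapply(wings, wing_length, numeric(1))

  genotyped <- stats::runif(n) < cfg$genotyped_fraction
  genotyped[f1_idx] <- TRUE   # hybrids are identified genetically
  gi <- which(genotyped)
  n_sites <- cfg$n_diagnostic_snps + cfg$n_background_snps
  dos <- matrix(NA_integer_, length(gi), n_sites)
  for (r in seq_along(gi)) {
    sp <- species[gi[r]]
    diagd <- switch(sp, A = rep(0L, cfg$n_diagnostic_snps),
                        B = rep(2L, cfg$n_diagnostic_snps),
                        hybrid = rep(1L, cfg$n_diagnostic_snps))
    dos[r, seq_len(cfg$n_diagnostic_snps)] <- diagd
  }
  p_bg <- stats::rbeta(cfg$n_background_snps, 2, 2)
  for (j in seq_len(cfg$n_background_snps))
    dos[, cfg$n_diagnostic_snps + j] <- stats::rbinom(length(gi), 2, p_bg[j])
  miss <- matrix(stats::runif(length(dos)) < 0.02, nrow(dos), ncol(dos))
  dos[miss] <- NA_integer_
  depth <- matrix(stats::rpois(length(dos), 15) + 1L, nrow(dos), ncol(dos))
  qual <- stats::runif(n_sites, 30, 60)
  site_ids <- c(sprintf("diag_%03d", seq_len(cfg$n_diagnostic_snps)),
                sprintf("bg_%03d", seq_len(cfg$n_background_snps)))
  genotypes <- genotype_matrix(dos, sample_ids = ids[gi], site_ids = site_ids,
                               depth = depth, qual = qual)

  # environmental gradients: logistic in x, centered west of the contact,
  # plus noise; three redundant copies exercise variable selection
  env_specs <- data.frame(
    name = c("temp_mean", "temp_season", "precip_summer", "evapo_july",
             "isothermality", "precip_season", "radiation"),
    amp = c(4, 3, -3.5, 2.5, -2, 3, 1.5),
    center = cfg$env_cline_center_km + c(0, 0.4, -0.3, 0.2, 0.5, -0.4, 0.1),
    width = c(3, 4, 3.5, 3, 5, 4, 6))
  env <- sapply(seq_len(nrow(env_specs)), function(j)
    sigmoid_mean(x, env_specs$center[j], env_specs$width[j], 0,
                 env_specs$amp[j]) + stats::rnorm(n, 0, cfg$env_noise_sd))
  colnames(env) <- env_specs$name
  env <- cbind(env,
    temp_mean_copy = env[, "temp_mean"] + stats::rnorm(n, 0, 0.05),
    temp_combo = env[, "temp_mean"] + env[, "temp_season"] +
      stats::rnorm(n, 0, 0.05),
    noise_var = stats::rnorm(n, 0, cfg$env_noise_sd))
  env <- data.frame(specimen_id = ids, env, stringsAsFactors = FALSE)

  specimens <- data.frame(
    specimen_id = ids, site = "contact_zone", population_type = "contact",
    species = species, genotyped = genotyped, distance_km = x,
    wing_length = wl, stringsAsFactors = FALSE)

  truth <- list(
    contact_km = cfg$contact_km, cline_width_km = cfg$cline_width_km,
    pmax_angle_deg = cfg$pmax_angle_deg,
    shape_divergence = cfg$shape_divergence,
    wing_pmax_A = as.vector(wings_dev$pmax_A),
    wing_pmax_B = as.vector(wings_dev$pmax_B),
    genital_pmax_A = as.vector(gen_dev$pmax_A),
    genital_pmax_B = as.vector(gen_dev$pmax_B),
    hybrid_ids = ids[f1_idx], n_f1 = n_f1,
    env_centers_km = stats::setNames(env_specs$center, env_specs$name),
    env_cline_center_km = cfg$env_cline_center_km,
    spot_landmarks = cfg$spot_landmarks,
    seed = cfg$seed)
  structure(list(specimens = specimens, wings = wings, genitalia = genitalia,
                 genotypes = genotypes, env = env, truth = truth,
                 config = cfg),
            class = "transect_simulation")
}

#' @export
print.transect_simulation <- function(x, ...) {
  cat(sprintf("<transect_simulation> %d specimens (%d A, %d B, %d hybrid), %d genotyped, %d SNPs\n",
              nrow(x$specimens), sum(x$specimens$species == "A"),
              sum(x$specimens$species == "B"),
              sum(x$specimens$species == "hybrid"),
              sum(x$specimens$genotyped), ncol(x$genotypes$dosages)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Produces the pipeline's file interface: `wings.tps`, `genitalia.tps`,
#' `specimens.csv`, `genotypes.vcf`, `env.csv`, `truth.json`.
#'
#' @param sim A `transect_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "transect_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tps(sim$wings, file.path(dir, "wings.tps"))
  write_tps(sim$genitalia, file.path(dir, "genitalia.tps"))
  utils::write.csv(sim$specimens, file.path(dir, "specimens.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$env, file.path(dir, "env.csv"), row.names = FALSE)
  write_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT:DP:GQ fields (DP/GQ when present), one
#' synthetic contig position per site. Round-trips through
#' [read_genotypes()].
#'
#' @param G A [genotype_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  has_dp <- !is.null(G$depth); has_gq <- !is.null(G$qual)
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_gq) "GQ"), collapse = ":")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if (has_gq) "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(ncol(G$dosages)), function(j) {
    d <- G$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    cells <- gt
    if (has_dp) cells <- paste(cells, G$depth[, j], sep = ":")
    if (has_gq) cells <- paste(cells, round(G$qual[j]), sep = ":")
    paste(c("chr1", j, G$site_ids[j], "A", "T", ".", "PASS", ".", fmt, cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
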