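default_pipeline_params <- function() {
  list(ci_level = 0.97, outlier_level = 0.95, window_size = 30L,
       window_step = 10L, n_boot = 499L, n_rep_niche = 1000L,
       r_max = 0.8, vif_max = 10, n_pcs_lda = 4L, n_pcs_pmatrix = 10L,
       cline_starts = 20L, maf_min = 0.04, max_missing = 0.60,
       gq_min = 20L, dp_min = 5, dp_max = 30)
}

# derive stage seeds from one global seed by fixed offsets
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 0L, assign = 101L, pmatrix = 211L, cline = 307L,
            windows = 401L, niche = 503L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

trait_block <- function(aligned, wl, specimens, spot = NULL) {
  X <- aligned
  if (!is.null(spot)) {
    cols <- as.vector(rbind(paste0("x", spot), paste0("y", spot)))
    X <- X[, cols, drop = FALSE]
  }
  size_correct(X, wl)
}

#' Run the full contact-zone analysis pipeline
#'
#' Executes the stages end to end on simulated or file-based inputs:
#' Procrustes alignment of wing and genital landmarks, wing-length size
#' correction, PCA per trait block (wing shape, orange-spot subset, genital
#' shape), genotype filtering and genomic PCA, F1 detection, discriminant
#' species assignment of ungenotyped specimens with a 97% confidence filter,
#' sigmoid cline fits (phenotypic PC1s, genomic PC1, environmental
#' variables), interspecific P-matrix comparisons with bootstrap
#' significance, the sliding-window P-matrix scan anchored at the genomic
#' cline center, and environmental niche overlap with similarity tests.
#' Deterministic given the config seed: stage seeds are derived from it by
#' fixed offsets.
#'
#' @param config One of: a [simulation_config] (simulate in memory), a
#'   `transect_simulation`, a path to a YAML file, or a list. YAML/list
#'   configs support keys `preset: paper_scale`, `simulate:` (arguments to
#'   [simulation_config()]), `seed:`, `out_dir:`, and `params:` overriding
#'   [default_pipeline_params()] entries.
#' @param out_dir Optional directory for per-stage outputs and the JSON
#'   report.
#' @param resume If `TRUE` and `out_dir` holds stage outputs from an
#'   identical config, the expensive window-scan stage is reloaded instead of
#'   recomputed.
#' @param verbose Emit per-stage progress messages (input counts, filter
#'   losses, seeds).
#' @return A list of class `pipeline_report`; see [report_summary()].
#' @export
run_pipeline <- function(config, out_dir = NULL, resume = FALSE,
                         verbose = FALSE) {
  log_info <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  params <- default_pipeline_params()
  seed <- 1L
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "simulation_config")) {
    sim <- simulate_transect(config)
    seed <- config$seed
  } else if (inherits(config, "transect_simulation")) {
    sim <- config
    seed <- sim$config$seed
  } else if (is.list(config)) {
    if (!is.null(config$seed)) seed <- as.integer(config$seed)
    if (!is.null(config$params))
      params[names(config$params)] <- config$params
    if (!is.null(config$out_dir) && is.null(out_dir)) out_dir <- config$out_dir
    if (identical(config$preset, "paper_scale")) {
      sim <- simulate_transect(paper_scale_preset(seed = seed))
    } else if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- seed
      sim <- simulate_transect(do.call(simulation_config, args))
    } else if (!is.null(config$inputs)) {
      sim <- load_pipeline_inputs(config$inputs)
    } else stop("config must name a preset, a simulate block, or inputs")
  } else stop("unsupported config type")

  specimens <- sim$specimens
  n0 <- nrow(specimens)
  counts <- list(input = n0)
  log_info("pipeline start: %d specimens, seed %d", n0, seed)

  ## --- morphometrics ------------------------------------------------------
  gpa_w <- generalized_procrustes(sim$wings)
  gpa_g <- generalized_procrustes(sim$genitalia)
  stopifnot(identical(gpa_w$specimen_ids, specimens$specimen_id))
  wl <- specimens$wing_length
  spot <- sim$truth$spot_landmarks %||% sim$config$spot_landmarks %||% 10:16
  blocks <- list(
    wing = trait_block(gpa_w$aligned, wl, specimens),
    spot = trait_block(gpa_w$aligned, wl, specimens, spot = spot),
    genital = trait_block(gpa_g$aligned, wl, specimens))
  pcas <- lapply(blocks, pca)
  counts$morphometrics <- nrow(blocks$wing)
  log_info("morphometrics: %d specimens aligned (wing GPA %d iter, genital %d iter)",
           counts$morphometrics, gpa_w$n_iter, gpa_g$n_iter)

  ## --- genotypes ----------------------------------------------------------
  filt <- filter_variants(sim$genotypes, maf_min = params$maf_min,
                          max_missing = params$max_missing,
                          gq_min = params$gq_min, dp_min = params$dp_min,
                          dp_max = params$dp_max)
  G <- filt$G
  gpca <- genotype_pca(G)
  set.seed(stage_seed(seed, "assign"))
  km <- stats::kmeans(gpca$scores[, 1], centers = 2, nstart = 5)
  gids <- G$sample_ids
  pos_by <- specimens$distance_km[match(gids, specimens$specimen_id)]
  west_cluster <- which.min(tapply(pos_by, km$cluster, mean))
  gen_label <- ifelse(km$cluster == west_cluster, "A", "B")
  gpca <- genotype_pca(G, orient_negative_ids = gids[gen_label == "A"])
  hyb <- hybrid_index(G, groupA_ids = gids[gen_label == "A"],
                      groupB_ids = gids[gen_label == "B"], samples = gids)
  f1_ids <- hyb$sample_id[hyb$call == "F1_candidate"]
  gen_label[gids %in% f1_ids] <- "hybrid"
  counts$genotypes <- length(gids)
  log_info("genotypes: %d individuals, %d -> %d sites (losses: %s); %d F1 candidate(s)",
           length(gids), ncol(sim$genotypes$dosages), ncol(G$dosages),
           paste(names(filt$losses), filt$losses, sep = "=", collapse = " "),
           length(f1_ids))

  ## --- assignment ---------------------------------------------------------
  npc <- params$n_pcs_lda
  take_pcs <- function(p, k, prefix) {
    s <- p$scores[, seq_len(k), drop = FALSE]
    colnames(s) <- paste0(prefix, "_", colnames(s))
    s
  }
  lda_traits <- cbind(take_pcs(pcas$wing, npc, "wing"),
                      take_pcs(pcas$spot, min(3L, npc), "spot"),
                      take_pcs(pcas$genital, npc, "genital"))
  rownames(lda_traits) <- specimens$specimen_id
  is_geno <- specimens$specimen_id %in% gids
  lab_geno <- gen_label[match(specimens$specimen_id[is_geno], gids)]
  train_keep <- is_geno & (specimens$specimen_id %in% gids[gen_label != "hybrid"])
  model <- fit_lda(lda_traits[train_keep, , drop = FALSE],
                   gen_label[match(specimens$specimen_id[train_keep], gids)])
  pred <- assign_species(model, lda_traits)
  species_final <- ifelse(is_geno, gen_label[match(specimens$specimen_id, gids)],
                          pred$label)
  non_hybrid <- species_final != "hybrid"
  keep_ci <- rep(FALSE, n0)
  keep_ci[non_hybrid] <- confidence_filter(
    lda_traits[non_hybrid, , drop = FALSE], species_final[non_hybrid],
    level = params$ci_level)
  specimens$species_assigned <- species_final
  specimens$retained <- keep_ci
  counts$assigned <- sum(non_hybrid)
  counts$retained_97ci <- sum(keep_ci)
  log_info("assignment (seed %d): %d assigned, %d retained at %.0f%% CI",
           stage_seed(seed, "assign"), counts$assigned, counts$retained_97ci,
           100 * params$ci_level)

  ## --- clines -------------------------------------------------------------
  cseed <- stage_seed(seed, "cline")
  ret <- which(keep_ci)
  fit_block_cline <- function(scores, idx) {
    y <- rescale01(scores[idx])
    x <- specimens$distance_km[idx]
    f <- fit_cline(x, y, n_starts = params$cline_starts, seed = cseed)
    if (f$model == "sigmoid") {
      f$center_ci <- as.numeric(profile_ci(f, x, y, "center_km"))
      f$width_ci <- as.numeric(profile_ci(f, x, y, "width_km"))
    }
    f
  }
  clines <- list(
    wing = fit_block_cline(pcas$wing$scores[, 1], ret),
    spot = fit_block_cline(pcas$spot$scores[, 1], ret),
    genital = fit_block_cline(pcas$genital$scores[, 1], ret))
  gidx <- match(gids, specimens$specimen_id)   # genomic cline includes hybrids
  ygen <- rescale01(gpca$scores[, 1])
  xgen <- specimens$distance_km[gidx]
  gcl <- fit_cline(xgen, ygen, n_starts = params$cline_starts, seed = cseed)
  if (gcl$model == "sigmoid") {
    gcl$center_ci <- as.numeric(profile_ci(gcl, xgen, ygen, "center_km"))
    gcl$width_ci <- as.numeric(profile_ci(gcl, xgen, ygen, "width_km"))
  }
  clines$genomic <- gcl
  log_info("clines (seed %d): centers %s km", cseed,
           paste(sprintf("%.2f", vapply(clines, function(f)
             if (is.na(f$center_km)) NA_real_ else f$center_km, numeric(1))),
             collapse = " / "))
  contact_km <- if (gcl$model == "sigmoid") gcl$center_km else
    stats::median(specimens$distance_km)

  ## --- P-matrix comparisons (transect-end interspecific) ------------------
  pm_seed <- stage_seed(seed, "pmatrix")
  size <- params$window_size
  pm_tables <- list()
  Xsp <- list(); possp <- list()
  for (block in names(blocks)) {
    per_species <- list()
    for (sp in c("A", "B")) {
      idx <- which(keep_ci & specimens$species_assigned == sp)
      Xi <- blocks[[block]][idx, , drop = FALSE]
      lof <- local_outlier_filter(Xi, level = params$outlier_level)
      idx <- idx[lof]
      p <- pca(blocks[[block]][idx, , drop = FALSE])
      k <- min(params$n_pcs_pmatrix, ncol(p$scores))
      per_species[[sp]] <- list(idx = idx,
                                scores = p$scores[, seq_len(k), drop = FALSE])
    }
    Xsp[[block]] <- lapply(per_species, `[[`, "scores")
    possp[[block]] <- lapply(per_species, function(e)
      specimens$distance_km[e$idx])
    # interspecific comparison using the transect-end reference sets, in a
    # common trait space (joint PCA of both species' filtered individuals)
    idxA <- per_species$A$idx; idxB <- per_species$B$idx
    joint <- pca(blocks[[block]][c(idxA, idxB), , drop = FALSE])
    k <- min(params$n_pcs_pmatrix, ncol(joint$scores))
    js <- joint$scores[, seq_len(k), drop = FALSE]
    posj <- specimens$distance_km[c(idxA, idxB)]
    endA <- order(abs(posj[seq_along(idxA)] - contact_km),
                  decreasing = TRUE)[seq_len(min(size, length(idxA)))]
    endB <- length(idxA) + order(abs(posj[-seq_along(idxA)] - contact_km),
                  decreasing = TRUE)[seq_len(min(size, length(idxB)))]
    bt <- bootstrap_compare(js[endA, , drop = FALSE], js[endB, , drop = FALSE],
                            "theta", n_boot = params$n_boot, seed = pm_seed)
    bd <- bootstrap_compare(js[endA, , drop = FALSE], js[endB, , drop = FALSE],
                            "distance", n_boot = params$n_boot, seed = pm_seed)
    pm_tables[[block]] <- data.frame(
      block = block, theta_deg = bt$observed, theta_p = bt$p_value,
      theta_significant = bt$significant, matrix_distance = bd$observed,
      distance_p = bd$p_value, distance_significant = bd$significant)
  }
  pm_table <- do.call(rbind, pm_tables)

  ## --- sliding windows ----------------------------------------------------
  wseed <- stage_seed(seed, "windows")
  cache_key <- paste(seed, size, params$window_step, params$n_boot,
                     round(contact_km, 6), sep = "_")
  cache_file <- if (!is.null(out_dir)) file.path(out_dir, "windows_cache.json")
  cached <- NULL
  if (resume && !is.null(cache_file) && file.exists(cache_file)) {
    raw <- jsonlite::read_json(cache_file, simplifyVector = TRUE)
    if (identical(raw$key, cache_key)) cached <- raw$scans
  }
  scans <- list(); trends <- list()
  for (block in names(blocks)) {
    scan <- if (!is.null(cached)) {
      s <- as.data.frame(cached[[block]])
      class(s) <- c("window_scan", class(s))
      s
    } else {
      window_scan(Xsp[[block]], possp[[block]], contact_km = contact_km,
                  size = size, step = params$window_step,
                  n_boot = params$n_boot, seed = wseed)
    }
    scans[[block]] <- scan
    trends[[block]] <- tryCatch(
      list(theta = trend_test(scan, "theta"),
           distance = trend_test(scan, "distance")),
      error = function(e) conditionMessage(e))
  }
  if (!is.null(cache_file) && is.null(cached)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(key = cache_key, scans = lapply(scans, as.data.frame)),
      cache_file, auto_unbox = TRUE, digits = NA)
  }

  log_info("window scan (seed %d): %d windows", wseed,
           sum(vapply(scans, nrow, integer(1))))

  ## --- niche overlap ------------------------------------------------------
  nseed <- stage_seed(seed, "niche")
  envm <- as.matrix(sim$env[, setdiff(names(sim$env), "specimen_id")])
  rownames(envm) <- sim$env$specimen_id
  vars <- select_variables(envm, r_max = params$r_max,
                           vif_max = params$vif_max)
  envs <- scale(envm[, vars, drop = FALSE])
  epca <- pca(envs, center = FALSE)
  exy <- epca$scores[, 1:2]
  occA <- exy[keep_ci & specimens$species_assigned == "A", , drop = FALSE]
  occB <- exy[keep_ci & specimens$species_assigned == "B", , drop = FALSE]
  niche <- similarity_test(occA, occB, exy, exy, n_rep = params$n_rep_niche,
                           seed = nseed, alternative = "lower")

  report <- structure(list(
    version = as.character(utils::packageVersion("clinemorph")),
    seed = seed, stage_seeds = vapply(
      c("assign", "pmatrix", "cline", "windows", "niche"),
      function(s) stage_seed(seed, s), numeric(1)),
    counts = counts, params = params,
    contact_km = contact_km,
    filter_losses = filt$losses,
    variance_fractions = c(
      wing_pc1 = unname(pcas$wing$var_fraction[1]),
      spot_pc1 = unname(pcas$spot$var_fraction[1]),
      genital_pc1 = unname(pcas$genital$var_fraction[1]),
      genomic_pc1 = unname(gpca$var_fraction[1])),
    lda_confusion = model$confusion,
    f1_candidates = f1_ids,
    hybrid_report = hyb,
    clines = clines,
    pmatrix_comparisons = pm_table,
    window_scans = scans,
    trend_tests = trends,
    niche = list(selected_variables = vars, D = niche$D, I = niche$I,
                 p_D = niche$p_D, p_I = niche$p_I,
                 alternative = niche$alternative),
    specimens = specimens,
    env_variable_names = vars),
    class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_json_body(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(report_summary(report), file.path(out_dir, "report.txt"))
    utils::write.csv(specimens, file.path(out_dir, "specimens_assigned.csv"),
                     row.names = FALSE)
  }
  report
}

load_pipeline_inputs <- function(inputs) {
  specimens <- read_specimens(inputs$specimens)
  wings <- read_tps(inputs$wings)
  genitalia <- read_tps(inputs$genitalia)
  genotypes <- read_genotypes(inputs$genotypes, format = "vcf")
  env <- utils::read.csv(inputs$env, stringsAsFactors = FALSE)
  structure(list(specimens = specimens, wings = wings, genitalia = genitalia,
                 genotypes = genotypes, env = env,
                 truth = NULL, config = NULL),
            class = "transect_simulation")
}

# serializable body of the report (excludes bulky per-specimen tables)
report_json_body <- function(r) {
  list(version = r$version, seed = r$seed, stage_seeds = as.list(r$stage_seeds),
       counts = r$counts, contact_km = r$contact_km,
       filter_losses = as.list(r$filter_losses),
       variance_fractions = as.list(r$variance_fractions),
       f1_candidates = r$f1_candidates,
       clines = lapply(r$clines, function(f)
         list(model = f$model, center_km = f$center_km,
              width_km = f$width_km, center_ci = f$center_ci,
              width_ci = f$width_ci, aic = f$aic,
              width_boundary = f$width_boundary)),
       pmatrix_comparisons = r$pmatrix_comparisons,
       window_scans = lapply(r$window_scans, as.data.frame),
       niche = r$niche)
}

#' Human-readable pipeline summary
#'
#' One line per result: cline centers with their 95% CIs and widths (printed
#' in meters when below 1 km), interspecific theta and matrix distances with
#' significance stars, window-scan trend tests, niche overlap indices.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @return Character vector of report lines (also printable via `cat`).
#' @export
report_summary <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  fmt_w <- function(w) {
    if (is.na(w)) return("NA")
    if (w < 1) sprintf("%.0f m", w * 1000) else sprintf("%.2f km", w)
  }
  star <- function(sig) if (isTRUE(sig)) "*" else "ns"
  out <- c(sprintf("contact-zone pipeline report (v%s, seed %d)",
                   report$version, report$seed),
           sprintf("specimens: %d in, %d assigned, %d retained at %.0f%% CI; %d genotyped; F1 candidates: %d",
                   report$counts$input, report$counts$assigned,
                   report$counts$retained_97ci,
                   100 * report$params$ci_level, report$counts$genotypes,
                   length(report$f1_candidates)),
           "clines (center [95% CI], width):")
  for (nm in names(report$clines)) {
    f <- report$clines[[nm]]
    if (f$model == "constant") {
      out <- c(out, sprintf("  %-8s constant model preferred (no cline)", nm))
    } else {
      ci <- if (!anyNA(f$center_ci))
        sprintf(" [%.2f, %.2f]", f$center_ci[1], f$center_ci[2]) else ""
      out <- c(out, sprintf("  %-8s %.2f km%s, width %s%s", nm, f$center_km,
                            ci, fmt_w(f$width_km),
                            if (f$width_boundary) " (at floor)" else ""))
    }
  }
  out <- c(out, "interspecific P-matrix comparisons (transect ends):")
  pm <- report$pmatrix_comparisons
  for (i in seq_len(nrow(pm)))
    out <- c(out, sprintf("  %-8s theta = %5.1f deg (%s), distance = %.2f (%s)",
                          pm$block[i], pm$theta_deg[i],
                          star(pm$theta_significant[i]), pm$matrix_distance[i],
                          star(pm$distance_significant[i])))
  if (length(report$window_scans) == 0L) {
    out <- c(out, "window scan: (no windows computed)")
  } else {
    out <- c(out, "sliding-window scan (significant windows / total):")
    for (nm in names(report$window_scans)) {
      sc <- report$window_scans[[nm]]
      out <- c(out, sprintf("  %-8s theta %d/%d, distance %d/%d", nm,
                            sum(sc$significant_theta), nrow(sc),
                            sum(sc$significant_distance), nrow(sc)))
    }
  }
  out <- c(out, sprintf("niche overlap (%d vars: %s): D = %.2f, I = %.2f; similarity p(%s) D %.3f / I %.3f",
                        length(report$niche$selected_variables),
                        paste(report$niche$selected_variables, collapse = ", "),
                        report$niche$D, report$niche$I,
                        report$niche$alternative,
                        report$niche$p_D, report$niche$p_I))
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(report_summary(x), sep = "\n")
  invisible(x)
}
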