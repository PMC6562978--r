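# Pipeline orchestration: simulate (or load) -> group -> metrics -> stats,
# writing CSV/GeoJSON/JSON artifacts and a run manifest with checksums.

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `seed` (mandatory), `n_sessions`, `session_sd`,
#' `chains`, `forest_gap`, `landscape_extent` and `profiles` (a map from
#' zone label to [disturbance_profile()] arguments). Alternatively
#' `observations` and `landscape` paths switch the pipeline to user data.
#'
#' @param path YAML file.
#' @return A [simulation_config()] with optional `data_paths` attribute.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed")
  profs <- if (!is.null(y$profiles)) {
    lapply(names(y$profiles), function(z)
      do.call(disturbance_profile, c(list(label = z), y$profiles[[z]])))
  } else default_profiles()
  cfg <- simulation_config(
    profiles = profs,
    n_sessions = y$n_sessions %||% 6,
    seed = y$seed,
    session_sd = y$session_sd %||% 0,
    landscape_extent = y$landscape_extent,
    chain_distances = unlist(y$chains %||% c(15, 30, 50)),
    forest_gap = y$forest_gap %||% 200)
  if (!is.null(y$observations))
    attr(cfg, "data_paths") <- list(observations = y$observations,
                                    landscape = y$landscape)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an observation table against the schema and landscape
#'
#' Checks column presence, demographic class enum, 0/1 flags, duplicate
#' ids within sessions, zone labels, and containment of out-of-pouch
#' points in their recorded zone's cleared polygon. Non-fatal: all
#' violations are returned as a report.
#'
#' @param observations Observation data frame.
#' @param landscape Optional `"mob_landscape"` for zone/containment checks.
#' @return Data frame (violation, detail); zero rows when well-formed.
#' @export
validate_observations <- function(observations, landscape = NULL) {
  v <- list()
  add <- function(what, detail) v[[length(v) + 1L]] <<-
    data.frame(violation = what, detail = detail)
  need <- c("session", "id", "x_m", "y_m", "zone", "demo_class",
            "in_pouch", "disturbed")
  miss <- setdiff(need, names(observations))
  if (length(miss)) {
    add("missing_columns", paste(miss, collapse = ", "))
    return(do.call(rbind, v))
  }
  bad_cls <- setdiff(unique(observations$demo_class), DEMO_CLASSES)
  for (b in bad_cls) add("demo_class_enum", b)
  for (col in c("in_pouch", "disturbed"))
    if (!all(observations[[col]] %in% c(0L, 1L)))
      add("flag_not_01", col)
  dup <- stats::aggregate(list(d = observations$id),
                          by = list(session = observations$session),
                          FUN = anyDuplicated)
  for (s in dup$session[dup$d > 0]) add("duplicate_ids", paste("session", s))
  if (!is.null(landscape)) {
    bad_zone <- setdiff(unique(observations$zone), landscape$zones$zone)
    for (b in bad_zone) add("unknown_zone", b)
    op <- observations[observations$in_pouch == 0L &
                         observations$zone %in% landscape$zones$zone, ]
    if (nrow(op)) {
      actual <- zone_of(op$x_m, op$y_m, landscape)
      out <- which(is.na(actual) | actual != op$zone)
      for (i in utils::head(out, 20))
        add("containment", sprintf("id %s not in cleared polygon of zone %s",
                                   op$id[i], op$zone[i]))
    }
  }
  if (!length(v))
    return(data.frame(violation = character(), detail = character()))
  do.call(rbind, v)
}

#' Write observations to CSV in the standard schema
#'
#' @param observations Observation table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(observations, path) {
  cols <- c("session", "id", "x_m", "y_m", "zone", "demo_class",
            "in_pouch", "disturbed", "mother_id")
  utils::write.csv(observations[, intersect(cols, names(observations))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.fit_to_list <- function(fit) {
  keep <- fit[c("family", "formula", "coef", "contrasts", "lrt_p",
                "sigma_session", "nobs", "anova", "method")]
  keep[!vapply(keep, is.null, logical(1))]
}

# A fit that cannot be computed (e.g. a zone-session with zero density
# makes the log undefined) is recorded, not fatal.
.safe_fit <- function(expr) {
  tryCatch(.fit_to_list(expr), error = function(e)
    list(error = conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) the survey; partition every session at each
#' chain distance; compute density, clusteredness, composition, positioning
#' and greenness metrics; fit the statistical layer; write all artifacts
#' plus a manifest with md5 checksums. Deterministic under a fixed seed.
#'
#' @param config A [simulation_config()] or path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding the config's.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]; timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- round(proc.time()[3] - t0, 2); t0 <<- proc.time()[3]
  }
  dp <- attr(config, "data_paths")
  if (is.null(dp)) {
    sv <- generate_survey(config)
    obs <- sv$observations; landscape <- sv$landscape
  } else {
    sv <- NULL
    obs <- read_observations_csv(dp$observations)
    landscape <- read_landscape_geojson(dp$landscape)
  }
  rep_v <- validate_observations(obs, landscape)
  if (nrow(rep_v))
    stop("input validation failed:\n",
         paste(rep_v$violation, rep_v$detail, sep = ": ", collapse = "\n"))
  write_landscape_geojson(landscape, file.path(out_dir, "landscape.geojson"))
  write_observations_csv(obs, file.path(out_dir, "observations.csv"))
  tick("simulate")

  chains <- config$chain_distances
  parts <- survey_partitions(obs, landscape, chains = chains)
  utils::write.csv(attr(parts, "assignments"),
                   file.path(out_dir, "assignments.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(parts), file.path(out_dir, "groups.csv"),
                   row.names = FALSE)
  tick("group")

  dens <- grazing_density(obs, landscape)
  utils::write.csv(dens, file.path(out_dir, "density.csv"), row.names = FALSE)
  comps <- survey_compositions(obs, landscape, chains = chains)
  utils::write.csv(mean_composition(comps),
                   file.path(out_dir, "composition_means.csv"),
                   row.names = FALSE)
  recs <- classify_positioning(obs, landscape, chain = min(chains))
  utils::write.csv(recs, file.path(out_dir, "positioning.csv"),
                   row.names = FALSE)
  utils::write.csv(positioning_proportions(recs),
                   file.path(out_dir, "positioning_proportions.csv"),
                   row.names = FALSE)
  tick("metrics")

  fits <- list(density_anova = .safe_fit(density_anova(dens)))
  fits$groupsize_lmm <- .safe_fit(groupsize_lmm(parts))
  moments <- list()
  for (ch in chains) {
    pch <- parts[parts$chain_m == ch, ]
    for (z in sort(unique(pch$zone))) {
      x <- pch$size[pch$zone == z]
      if (length(x) >= 20 && stats::var(x) > 0) {
        sk <- dagostino_skewness(x); ku <- anscombe_kurtosis(x)
        moments[[length(moments) + 1L]] <- data.frame(
          zone = z, chain_m = ch, skew = sk$statistic, skew_p = sk$p.value,
          kurtosis = ku$statistic, kurtosis_p = ku$p.value)
      }
    }
    fits[[paste0("clusteredness_lmm_", ch)]] <-
      .safe_fit(clusteredness_lmm(pch))
    fits[[paste0("nb_cover_glmm_", ch)]] <-
      .safe_fit(groupsize_cover_glmm(pch))
    for (k in DEMO_CLASSES)
      fits[[paste0("demography_lmm_", ch, "_", k)]] <-
        .safe_fit(demography_lmm(comps[comps$chain_m == ch, ], k))
  }
  moments <- if (length(moments)) do.call(rbind, moments) else
    data.frame(zone = character(), chain_m = numeric(), skew = numeric(),
               skew_p = numeric(), kurtosis = numeric(),
               kurtosis_p = numeric())
  utils::write.csv(moments, file.path(out_dir, "moment_tests.csv"),
                   row.names = FALSE)
  fits$positioning_gam <- .safe_fit(positioning_gam(recs))
  if (!is.null(sv)) {  # planted per-group greenness exists only when simulated
    gfit <- tryCatch(greenness_models(sv$groups), error = function(e) NULL)
    if (!is.null(gfit)) {
      fits$greenness_lmm <- .fit_to_list(gfit$greenness)
      fits$size_vs_greenness_lmm <- .fit_to_list(gfit$size_vs_greenness)
    }
  }
  jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  tick("stats")

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    seed = config$seed,
    n_sessions = config$n_sessions,
    chains = chains,
    counts = list(individuals = nrow(obs),
                  groups_per_chain = as.list(table(parts$chain_m))),
    stage_seconds = as.list(timings),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
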