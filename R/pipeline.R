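#' Reproducible run configuration
#'
#' A single serializable configuration object driving [run_pipeline()].
#' Exactly one input mode is allowed: `"simulate"` (generate ground truth
#' and stacks), `"stacks"` (classify TIFF stacks from disk), or
#' `"counts_csv"` (start from a pre-tabulated classification table, which
#' bypasses imaging entirely).
#'
#' @param mode one of `"simulate"`, `"stacks"`, `"counts_csv"`.
#' @param paths named list: `stacks` (directory of `.tif` + sidecars,
#'   stacks mode), `counts_csv` (CSV with columns `animal_id, region,
#'   condition, pretreatment, neg, nuc, cyt, dob`), `rois` (ROI polygon
#'   JSON, optional).
#' @param sim named list of [sim_config()] overrides (simulate mode).
#' @param n_animals number of simulated animals (simulate mode).
#' @param classify named list of [classify_options()] overrides.
#' @param sisc named list: `exclude_conditions` (default `"CC"`).
#' @param synapto named list: `true_fractions` (simulate mode),
#'   `enlargement`.
#' @param stats named list: `posthoc` (`"fisher_lsd"`, `"bonferroni"`,
#'   `"none"`).
#' @param seed integer master seed; all per-animal seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "stacks", "counts_csv"),
                       paths = list(), sim = list(), n_animals = 3L,
                       classify = list(), sisc = list(), synapto = list(),
                       stats = list(), seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "stacks" && is.null(paths$stacks))
    stop("stacks mode requires `paths$stacks`", call. = FALSE)
  if (mode == "counts_csv" && is.null(paths$counts_csv))
    stop("counts_csv mode requires `paths$counts_csv`", call. = FALSE)
  if (mode == "counts_csv" && !file.exists(paths$counts_csv))
    stop("counts CSV not found: ", paths$counts_csv, call. = FALSE)
  structure(list(mode = mode, paths = paths, sim = sim,
                 n_animals = as.integer(n_animals), classify = classify,
                 sisc = sisc, synapto = synapto, stats = stats,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / deserialize a run configuration
#'
#' JSON round-trip: `read_run_config(write_run_config(cfg, path))` is
#' identical to `cfg`.
#'
#' @param config a [run_config()].
#' @param path JSON path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the config.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_list <- function(x) if (is.null(x)) list() else as.list(x)
  run_config(mode = raw$mode, paths = as_list(raw$paths),
             sim = as_list(raw$sim), n_animals = raw$n_animals,
             classify = as_list(raw$classify), sisc = as_list(raw$sisc),
             synapto = as_list(raw$synapto), stats = as_list(raw$stats),
             seed = raw$seed)
}

#' Run the catFISH analysis pipeline
#'
#' Orchestrates simulate/classify/score/quantify as one reproducible run.
#' Writes into `out_dir`: `cells.csv` (per-cell classifications),
#' `counts.csv` (per-animal tallies), `sisc.csv` (similarity scores),
#' `roi_measures.csv` (synaptophysin/Map2 area fractions), `stats.json`
#' (summary statistics), and `manifest.json` (config echo, config hash,
#' seed, package version, excluded-unit log). Identical config and seed
#' yield byte-identical CSVs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; the run artifacts live there.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  opts <- do.call(classify_options, config$classify)
  excluded <- list()
  cells <- NULL; counts <- NULL; roi_measures <- NULL

  if (config$mode == "simulate") {
    sim_args <- config$sim
    per_animal <- list(); count_rows <- list()
    for (a in seq_len(config$n_animals)) {
      sim_args$seed <- config$seed + 1000L * a
      cfg <- do.call(sim_config, sim_args)
      truth <- simulate_labels(cfg)
      st <- render_stack(truth, cfg)
      cl <- classify_stack(st, opts)
      cl$animal_id <- sprintf("A%02d", a)
      per_animal[[a]] <- cl
      count_rows[[a]] <- tally_cells(cl, animal_id = sprintf("A%02d", a),
                                     region = "CA1", condition = "AA",
                                     pretreatment = "WM")
      excluded[[length(excluded) + 1L]] <- list(
        unit = sprintf("A%02d", a), reason = "glia_or_dissector",
        n = sum(is.na(cl$label)))
    }
    cells <- do.call(rbind, per_animal)
    counts <- do.call(rbind, count_rows)
    # one synthetic mosaic with known fractions for the densitometry stage
    fr <- config$synapto$true_fractions %||%
      stats::setNames(seq(10, 36, length.out = 14), names(default_roi_spec()))
    rois <- default_roi_spec()[names(fr)]
    mz <- render_mosaic(rois, fr, seed = config$seed + 77L,
                        enlargement = config$synapto$enlargement %||% 0.10)
    roi_measures <- measure_mosaic(mz, mz$rois,
                                   enlargement = config$synapto$enlargement %||% 0.10,
                                   slide_id = "sim", animal_id = "A01",
                                   pretreatment = "WM")
  } else if (config$mode == "stacks") {
    files <- sort(list.files(config$paths$stacks, pattern = "\\.tiff?$",
                             full.names = TRUE))
    if (!length(files))
      stop("no TIFF stacks found in ", config$paths$stacks, call. = FALSE)
    per_stack <- lapply(files, function(f) {
      cl <- classify_stack(read_stack(f), opts)
      cl$animal_id <- sub("_.*$", "", basename(tools::file_path_sans_ext(f)))
      cl
    })
    cells <- do.call(rbind, per_stack)
    counts <- do.call(rbind, lapply(split(cells, cells$animal_id), function(df)
      tally_cells(df, animal_id = df$animal_id[1], region = "CA1",
                  condition = NA_character_, pretreatment = NA_character_)))
  } else {  # counts_csv
    raw <- utils::read.csv(config$paths$counts_csv)
    need <- c("animal_id", "region", "condition", "pretreatment",
              "neg", "nuc", "cyt", "dob")
    if (!all(need %in% names(raw)))
      stop("counts CSV must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    counts <- cell_counts(raw$neg, raw$nuc, raw$cyt, raw$dob,
                          animal_id = raw$animal_id, region = raw$region,
                          condition = raw$condition,
                          pretreatment = raw$pretreatment)
  }

  excl <- config$sisc$exclude_conditions %||% "CC"
  sisc <- sisc_table(counts, exclude_conditions = excl)
  n_undef <- sum(sisc$undefined)
  if (n_undef)
    excluded[[length(excluded) + 1L]] <- list(
      unit = "sisc", reason = "undefined_score", n = n_undef)

  if (!is.null(cells)) utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                                        row.names = FALSE)
  utils::write.csv(counts, file.path(out_dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(sisc, file.path(out_dir, "sisc.csv"), row.names = FALSE)
  if (!is.null(roi_measures))
    utils::write.csv(roi_measures, file.path(out_dir, "roi_measures.csv"),
                     row.names = FALSE)

  ok <- !sisc$undefined
  stats_out <- list(
    n_units = nrow(sisc), n_undefined_sisc = n_undef,
    sisc_mean = if (any(ok)) mean(sisc$sisc[ok]) else NA,
    sisc_sem = if (sum(ok) > 1) stats::sd(sisc$sisc[ok]) / sqrt(sum(ok)) else NA,
    epoch1_mean = mean(sisc$epoch1), epoch2_mean = mean(sisc$epoch2))
  if (!is.null(roi_measures))
    stats_out$fraction_mean <- mean(roi_measures$fraction)
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  cfg_path <- file.path(out_dir, "config.json")
  write_run_config(config, cfg_path)
  manifest <- list(
    config = unclass(config),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("catfishr")),
    excluded = excluded)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Simulated 3 x 3 pretreatment-by-condition experiment
#'
#' Emulates the full analysis shape of a two-epoch exploration study:
#' three behavioral pretreatments (IC, SC, WM) crossed with three double
#' exploration conditions (AA: same box same room; AA': different box same
#' room; AB: different box different room). Each design cell receives its
#' own ensemble-overlap parameter `kappa[pretreatment, condition]`;
#' `n_animals` animals are simulated per cell (labels only, no imaging),
#' scored with [similarity_score()], summarized as mean +/- s.e.m., and
#' compared by [two_way_anova()].
#'
#' @param kappa 3 x 3 numeric matrix with rownames
#'   `c("IC", "SC", "WM")` and colnames `c("AA", "AA'", "AB")` (any row
#'   and column names are accepted and used as factor levels).
#' @param n_animals animals per design cell.
#' @param n_cells neurons analyzed per animal.
#' @param p1,p2 marginal activation probabilities.
#' @param seed master seed.
#' @return A list with `animals` (per-animal SiSc table), `summary`
#'   (per-cell mean, s.e.m., n), and `anova` (the two-way result).
#' @examples
#' k <- matrix(c(0.3, 0.3, 0.2, 0.5, 0.4, 0.3, 0.9, 0.8, 0.1),
#'             nrow = 3, byrow = TRUE,
#'             dimnames = list(c("IC", "SC", "WM"), c("AA", "AA'", "AB")))
#' ex <- experiment_3x3(k, n_animals = 3, n_cells = 400, seed = 1)
#' ex$summary
#' @export
experiment_3x3 <- function(kappa, n_animals = 4L, n_cells = 1000L,
                           p1 = 0.3, p2 = 0.3, seed = 1L) {
  if (!is.matrix(kappa) || is.null(rownames(kappa)) || is.null(colnames(kappa)))
    stop("`kappa` must be a matrix with pretreatment rownames and condition colnames",
         call. = FALSE)
  if (anyNA(kappa))
    stop("missing kappa for some design cell(s)", call. = FALSE)
  if (n_animals < 2)
    stop("the two-way ANOVA needs at least 2 animals per design cell",
         call. = FALSE)
  rows <- list()
  i <- 0L
  for (pre in rownames(kappa)) for (cond in colnames(kappa)) {
    for (a in seq_len(n_animals)) {
      i <- i + 1L
      cfg <- sim_config(n_cells = n_cells, p1 = p1, p2 = p2,
                        kappa = kappa[pre, cond], glia_fraction = 0,
                        seed = seed + i)
      counts <- truth_counts(simulate_labels(cfg),
                             animal_id = sprintf("%s_%s_%02d", pre, cond, a),
                             region = "CA1", condition = cond,
                             pretreatment = pre)
      rows[[i]] <- similarity_score(counts)
    }
  }
  animals <- do.call(rbind, rows)
  ok <- !animals$undefined
  spl <- split(animals$sisc[ok],
               list(pretreatment = animals$pretreatment[ok],
                    condition = animals$condition[ok]))
  summary <- do.call(rbind, lapply(names(spl), function(nm) {
    v <- spl[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(pretreatment = parts[1], condition = parts[2],
               mean_sisc = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  }))
  rownames(summary) <- NULL
  anova <- two_way_anova(animals[ok, ], "sisc", "pretreatment", "condition")
  list(animals = animals, summary = summary, anova = anova)
}
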