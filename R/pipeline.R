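#' Default trait polarities for the computing phenotypic traits
#'
#' Polarity declares whether a trait rises (`positive`) or falls
#' (`negative`) with yield-referenced tolerance. Structural traits and the
#' chlorophyll / LAI / water / biomass / red-edge indices are positive;
#' the anthocyanin, carotenoid and Carter stress ratios (ARI, CRI, CTR)
#' rise under stress and are negative.
#'
#' @param trait_names traits to look up; defaults to the 19-trait CPT set.
#' @return Named character vector of `"positive"` / `"negative"`, with
#'   `"positive"` for unknown names.
#' @export
default_polarity <- function(trait_names = NULL) {
  if (is.null(trait_names)) trait_names <- .cpt_trait_names(19L)
  neg <- c("ARI", "CRI", "CTR")
  stats::setNames(ifelse(trait_names %in% neg, "negative", "positive"),
                  trait_names)
}

#' Pipeline run configuration
#'
#' Bundles every tunable constant of the pipeline: the TVI segmentation
#' threshold, the height/area grid cell, the point-cloud filter chain, the
#' membership breakpoints, the grade scores, the PCA reference trait and
#' the seed.
#'
#' @param tvi_threshold TVI segmentation cut (default 10.6).
#' @param grid_cell height/area grid cell, cm (default 0.5).
#' @param filter a [filter_config()].
#' @param membership a [membership_params()].
#' @param evaluation an [evaluation_set()].
#' @param reference_trait PC1 orientation trait (default "NDVI").
#' @param seed integer seed echoed into reports.
#' @return A `run_config` list.
#' @export
run_config <- function(tvi_threshold = 10.6, grid_cell = 0.5,
                       filter = filter_config(),
                       membership = membership_params(),
                       evaluation = evaluation_set(),
                       reference_trait = "NDVI", seed = 1L) {
  stopifnot(is.numeric(tvi_threshold), grid_cell > 0,
            inherits(filter, "filter_config"),
            inherits(membership, "membership_params"),
            inherits(evaluation, "evaluation_set"))
  structure(list(tvi_threshold = tvi_threshold, grid_cell = grid_cell,
                 filter = filter, membership = membership,
                 evaluation = evaluation,
                 reference_trait = reference_trait,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration as JSON
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
.config_as_list <- function(x) {
  if (is.list(x)) lapply(unclass(x), .config_as_list) else x
}

write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(.config_as_list(config), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' Unknown keys are rejected so stale or misspelled configs fail loudly.
#'
#' @param path JSON file written by [write_run_config()] (possibly edited).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("tvi_threshold", "grid_cell", "filter", "membership",
             "evaluation", "reference_trait", "seed")
  bad <- setdiff(names(j), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  fl <- j$filter; mb <- j$membership; ev <- j$evaluation
  if (!is.null(fl)) {
    bad <- setdiff(names(fl), c("knn", "std_multiplier", "voxel_size",
                                "canopy_fraction", "mls_radius"))
    if (length(bad))
      stop("unknown filter key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(mb)) {
    bad <- setdiff(names(mb), c("breakpoints", "fuzzy_halfwidth"))
    if (length(bad))
      stop("unknown membership key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(ev)) {
    bad <- setdiff(names(ev), c("grades", "scores"))
    if (length(bad))
      stop("unknown evaluation key(s): ", paste(bad, collapse = ", "))
  }
  dflt <- run_config()
  run_config(
    tvi_threshold = j$tvi_threshold %||% dflt$tvi_threshold,
    grid_cell = j$grid_cell %||% dflt$grid_cell,
    filter = if (is.null(fl)) dflt$filter else do.call(filter_config, fl),
    membership = if (is.null(mb)) dflt$membership
                 else membership_params(mb$breakpoints,
                                        mb$fuzzy_halfwidth %||% 0.05),
    evaluation = if (is.null(ev)) dflt$evaluation
                 else evaluation_set(ev$grades, ev$scores),
    reference_trait = j$reference_trait %||% dflt$reference_trait,
    seed = j$seed %||% dflt$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a CSV trait table (plus optional polarity file)
#'
#' @param path CSV with a header row, a `sample_id` column and one numeric
#'   column per trait.
#' @param polarity_path optional two-column CSV (`trait`, `polarity`); traits
#'   not listed default per [default_polarity()].
#' @return A [trait_matrix].
#' @export
read_trait_csv <- function(path, polarity_path = NULL) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("trait CSV ", path, " lacks a 'sample_id' column")
  ids <- as.character(df$sample_id)
  v <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  pol <- default_polarity(colnames(v))
  if (!is.null(polarity_path)) {
    if (!file.exists(polarity_path))
      stop("polarity file not found: ", polarity_path)
    pf <- utils::read.csv(polarity_path, check.names = FALSE)
    if (!all(c("trait", "polarity") %in% names(pf)))
      stop("polarity CSV needs 'trait' and 'polarity' columns")
    hit <- match(colnames(v), pf$trait)
    pol[!is.na(hit)] <- as.character(pf$polarity[hit[!is.na(hit)]])
  }
  trait_matrix(v, ids, pol)
}

#' Write a trait table as CSV
#' @param matrix a [trait_matrix].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "trait_matrix"))
  df <- data.frame(sample_id = matrix$sample_ids, matrix$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Extract the 19-trait CPT row of one sample (3 structural + 16 spectral).
.sample_traits <- function(sample_id, cube_path, cloud_path, config) {
  cube <- load_cube(cube_path)
  tvi <- compute_index(cube, "TVI")
  mask <- segment_vegetation(tvi, config$tvi_threshold)
  spec_tr <- extract_spectral_traits(cube, mask, sample_id)
  cloud <- load_points(cloud_path, sample_id = sample_id)
  str_tr <- extract_structural_traits(cloud, config$filter, config$grid_cell)
  c(Height = str_tr$height, `Leaf-area` = str_tr$canopy_leaf_area,
    Volume = str_tr$volume, spec_tr$values)
}

#' Run the full evaluation pipeline
#'
#' For every manifest sample: extract the 16 spectral traits from its cube
#' and the 3 structural traits from its cloud, assemble the trait matrix,
#' grade it with FCE-E, compute the trait-statistics table and the PCA
#' composite baseline, and (when a second trait table is supplied) the
#' consistency rate between the two FCE-E rating sets. All outputs land in
#' `out_dir` with the resolved configuration echoed into `report.json`;
#' any stage error aborts the run, names the failing sample, and removes
#' partial outputs.
#'
#' @param config a [run_config()].
#' @param manifest list with `samples` (data frame: `sample_id`, `cube`,
#'   `cloud`) and/or `traits` (path to a trait CSV used instead of
#'   extraction); optional `traits_b` (second trait CSV, e.g. measured
#'   typical traits, rated with the same model for comparison) and
#'   `polarity` (polarity CSV applied to CSV-loaded tables).
#' @param out_dir output directory (created).
#' @return Invisibly, a list with `traits`, `fce`, `stats`, `pca` and
#'   `rank_agreement` (both NULL with fewer than 3 samples), and
#'   `consistency` (NULL without `traits_b`).
#' @export
run_pipeline <- function(config, manifest, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  emit <- function(path) written <<- c(written, path)

  if (!is.null(manifest$samples)) {
    s <- manifest$samples
    if (!all(c("sample_id", "cube", "cloud") %in% names(s)))
      stop("manifest samples need sample_id, cube, cloud columns")
    for (f in c(s$cube, s$cloud))
      if (!file.exists(f) && !file.exists(paste0(f, ".hdr")))
        stop("manifest references a missing file: ", f)
    message("extracting traits for ", nrow(s), " sample(s)")
    rows <- lapply(seq_len(nrow(s)), function(i)
      tryCatch(.sample_traits(s$sample_id[i], s$cube[i], s$cloud[i], config),
               error = function(e)
                 stop("sample ", s$sample_id[i], ": ", conditionMessage(e),
                      call. = FALSE)))
    vals <- do.call(rbind, rows)
    tm <- trait_matrix(vals, s$sample_id,
                       default_polarity(colnames(vals)))
  } else if (!is.null(manifest$traits)) {
    message("loading trait table ", manifest$traits)
    tm <- read_trait_csv(manifest$traits, manifest$polarity)
  } else stop("manifest must provide samples or a traits CSV")

  emit(write_trait_csv(tm, file.path(out_dir, "traits.csv")))

  message("FCE-E evaluation of ", length(tm$sample_ids), " sample(s)")
  fce <- fce_evaluate(tm, config$membership, config$evaluation)
  ev <- fce$evaluations
  utils::write.csv(ev, file.path(out_dir, "ratings.csv"),
                   row.names = FALSE, quote = FALSE)
  emit(file.path(out_dir, "ratings.csv"))

  ref <- if (config$reference_trait %in% tm$trait_names)
    config$reference_trait else tm$trait_names[1L]
  # the PCA baseline (and its variance-contribution column) needs >= 3
  # samples; with fewer, the stats table carries NA contributions and the
  # baseline is skipped
  pca <- NULL
  if (length(tm$sample_ids) >= 3L) {
    stats_tab <- trait_stats_table(tm, ref)
    pca <- pca_composite(tm, ref)
  } else {
    message("fewer than 3 samples: skipping the PCA baseline")
    std <- suppressWarnings(standardize(tm))
    stats_tab <- data.frame(
      trait = tm$trait_names,
      cv = as.numeric(apply(tm$values, 2, coefficient_of_variation)),
      h = .entropy_divergence(std$values)$divergence,
      var = NA_real_, stringsAsFactors = FALSE)
  }
  utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                   row.names = FALSE, quote = FALSE)
  emit(file.path(out_dir, "stats.csv"))

  if (!is.null(pca)) {
    utils::write.csv(data.frame(sample_id = pca$sample_ids,
                                pc1_score = unname(pca$pc1_scores),
                                rank = unname(pca$ranks)),
                     file.path(out_dir, "pca.csv"),
                     row.names = FALSE, quote = FALSE)
    emit(file.path(out_dir, "pca.csv"))
  }

  consistency <- NULL
  if (!is.null(manifest$traits_b)) {
    tm_b <- read_trait_csv(manifest$traits_b, manifest$polarity)
    fce_b <- fce_evaluate(tm_b, config$membership, config$evaluation)
    consistency <- consistency_rate(fce, fce_b)
    utils::write.csv(fce_b$evaluations,
                     file.path(out_dir, "ratings_b.csv"),
                     row.names = FALSE, quote = FALSE)
    emit(file.path(out_dir, "ratings_b.csv"))
  }

  report <- list(
    config = .config_as_list(config),
    n_samples = length(tm$sample_ids),
    traits = tm$trait_names,
    weights = as.list(fce$weights$weights),
    divergences = as.list(fce$weights$divergences),
    entropies = as.list(fce$weights$entropies),
    pca_explained_fraction = if (!is.null(pca)) pca$explained_fraction,
    rank_agreement = if (!is.null(pca)) rank_agreement(fce, pca),
    consistency_rate = consistency)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit(file.path(out_dir, "report.json"))

  ok <- TRUE
  invisible(list(traits = tm, fce = fce, stats = stats_tab, pca = pca,
                 rank_agreement = report$rank_agreement,
                 consistency = consistency))
}
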