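#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run: input mode, calibration,
#' segmentation, GLCM and statistics settings, output directory and the
#' single global seed from which all per-object seeds are fanned out.
#'
#' @param mode `"synthetic"` (generate a filling cohort) or `"images"`
#'   (load masks/micrographs listed in a sample sheet).
#' @param out_dir output directory for CSVs, summary JSON and log.
#' @param seed global integer seed.
#' @param series a [filling_series_params()]; synthetic mode only.
#'   Its own seed is overridden by `seed`.
#' @param n_intervals panicle intervals in synthetic mode (default 4).
#' @param sample_sheet path to a CSV with columns `path`, `source_id`,
#'   `stage`, `interval` and optionally `scale_mm_per_px`; images mode.
#' @param scale_mm_per_px calibration used when the sheet has no
#'   per-image scale, and for synthetic texture bookkeeping.
#' @param threshold `"otsu"` or a fixed gray level 0..255 (images mode;
#'   ignored for files that are already binary masks — values are
#'   thresholded at 128 by [read_mask()] when `input = "masks"`).
#' @param input `"masks"` (sheet lists binary mask images; default) or
#'   `"micrographs"` (grayscale images to be binarized and extracted).
#' @param invert,fill_holes segmentation flags, see [binarize()] and
#'   [extract_roi()].
#' @param glcm_Ng,glcm_offset,glcm_symmetric GLCM settings, see
#'   [glcm()].
#' @param texture_org_start,texture_org_end organization of synthetic
#'   endosperm patches at the first/last stage (dorsal region); the
#'   ventral (white-belly) region runs at `texture_ventral_shift` lower
#'   organization. Defaults 0.25 -> 0.85 rising with filling.
#' @param texture_ventral_shift see above (default 0.15).
#' @param n_texture_patches patches per stage x region (default 5).
#' @param texture_size_px patch edge length (default 128).
#' @param gate,alpha,adjust statistics settings, see [group_table()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "images"),
                       out_dir = tempfile("grainmorph_run_"),
                       seed = 1L,
                       series = filling_series_params(),
                       n_intervals = 4L,
                       sample_sheet = NULL,
                       scale_mm_per_px = 0.01,
                       threshold = "otsu",
                       input = c("masks", "micrographs"),
                       invert = FALSE,
                       fill_holes = TRUE,
                       glcm_Ng = 8L,
                       glcm_offset = c(1, 0),
                       glcm_symmetric = TRUE,
                       texture_org_start = 0.25,
                       texture_org_end = 0.85,
                       texture_ventral_shift = 0.15,
                       n_texture_patches = 5L,
                       texture_size_px = 128L,
                       gate = c("kruskal", "anova"),
                       alpha = 0.05,
                       adjust = c("none", "bonferroni", "holm")) {
  mode <- match.arg(mode)
  input <- match.arg(input)
  gate <- match.arg(gate)
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (mode == "images") {
    if (is.null(sample_sheet) || !file.exists(sample_sheet))
      stop("images mode requires an existing `sample_sheet` CSV")
  }
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 series = series, n_intervals = as.integer(n_intervals),
                 sample_sheet = sample_sheet,
                 scale_mm_per_px = scale_mm_per_px,
                 threshold = threshold, input = input,
                 invert = invert, fill_holes = fill_holes,
                 glcm_Ng = as.integer(glcm_Ng),
                 glcm_offset = as.integer(glcm_offset),
                 glcm_symmetric = glcm_symmetric,
                 texture_org_start = texture_org_start,
                 texture_org_end = texture_org_end,
                 texture_ventral_shift = texture_ventral_shift,
                 n_texture_patches = as.integer(n_texture_patches),
                 texture_size_px = as.integer(texture_size_px),
                 gate = gate, alpha = alpha, adjust = adjust),
            class = "run_config")
}

# 6-significant-digit formatting for diff-stable CSV artifacts
.write_csv6 <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.texture_table <- function(config) {
  stages <- config$series$stages
  S <- length(stages)
  rows <- list()
  for (s in seq_len(S)) {
    f <- if (S == 1L) 0 else (s - 1) / (S - 1)
    org_d <- config$texture_org_start +
      f * (config$texture_org_end - config$texture_org_start)
    for (region in c("dorsal", "ventral")) {
      org <- if (region == "dorsal") org_d else
        max(0, org_d - config$texture_ventral_shift)
      for (r in seq_len(config$n_texture_patches)) {
        tp <- texture_patch_params(
          size_px = config$texture_size_px, organization = org,
          gray_levels = config$glcm_Ng,
          seed = .fanout_seed(config$seed, "texture", s, region, r))
        patch <- make_texture_patch(tp)
        rec <- texture_record(
          patch, patch_id = sprintf("%s_%s_p%02d", stages[s], region, r),
          region = region, Ng = config$glcm_Ng,
          offset = config$glcm_offset,
          symmetric = config$glcm_symmetric)
        rec$stage <- stages[s]
        rec$organization <- org
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  do.call(rbind, rows)
}

.load_sheet_masks <- function(config) {
  sheet <- utils::read.csv(config$sample_sheet, stringsAsFactors = FALSE)
  if (nrow(sheet) == 0L) stop("sample sheet is empty")
  need <- c("path", "source_id", "stage", "interval")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (!("scale_mm_per_px" %in% names(sheet)))
    sheet$scale_mm_per_px <- config$scale_mm_per_px
  masks <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$source_id[i]
    res <- tryCatch({
      if (config$input == "masks") {
        read_mask(sheet$path[i], sheet$scale_mm_per_px[i], sid)
      } else {
        img <- load_image(sheet$path[i], sheet$scale_mm_per_px[i], sid)
        mk <- if (identical(config$threshold, "otsu")) {
          binarize(img, "otsu", invert = config$invert)
        } else {
          binarize(img, "fixed", threshold = as.numeric(config$threshold),
                   invert = config$invert)
        }
        extract_roi(mk, fill_holes = config$fill_holes)
      }
    }, error = function(e) {
      stop(sprintf("stage 'segmentation' failed for source_id '%s': %s",
                   sid, conditionMessage(e)), call. = FALSE)
    })
    masks[[i]] <- res
  }
  list(masks = masks, sheet = sheet)
}

#' Run the full characterization pipeline
#'
#' Synthesizes (or loads) grain cross-section masks, measures the seven
#' morphometric descriptors, the per-grain fractal dimensions and the
#' ensemble power-law exponents, computes GLCM texture of endosperm
#' patches (synthetic mode), and produces grouped Table-1-style
#' summaries with Dunn's-test significance letters. All outputs are
#' deterministic given the configuration and seed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `morphometry`, `fractal`, `texture`
#'   (synthetic mode), `table1`, `ensembles`, `trends` data frames,
#'   `summary` (the JSON-ready list) and `paths` of the written
#'   artifacts: `morphometry.csv`, `fractal.csv`, `texture.csv`,
#'   `table1_style.csv`, `summary.json`, `effective_config.json`,
#'   `run.log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon), add = TRUE)
  logmsg <- function(...) writeLines(sprintf(...), logcon)
  logmsg("grainmorph pipeline, mode = %s, seed = %d", config$mode,
         config$seed)

  if (config$mode == "synthetic") {
    ser <- config$series
    ser$seed <- config$seed
    cohort <- make_filling_cohort(ser, n_intervals = config$n_intervals)
    masks <- cohort$masks
    sheet <- cohort$sheet
    logmsg("generated %d synthetic masks (%d stages x %d intervals)",
           length(masks), length(ser$stages), config$n_intervals)
  } else {
    loaded <- .load_sheet_masks(config)
    masks <- loaded$masks
    sheet <- loaded$sheet
    logmsg("loaded %d masks from %s", length(masks), config$sample_sheet)
  }

  morpho <- measure_masks(masks)
  morpho <- merge(sheet[c("source_id", "stage", "interval")], morpho,
                  by = "source_id", sort = FALSE)
  morpho <- morpho[order(morpho$stage, morpho$interval), ]
  frac <- fractal_records(morpho)
  logmsg("measured %d grains", nrow(morpho))

  ens <- list()
  for (st in unique(frac$stage)) for (iv in unique(frac$interval)) {
    sub <- frac[frac$stage == st & frac$interval == iv, ]
    if (nrow(sub) >= 3L) {
      e <- tryCatch(ensemble_exponents(sub), error = function(e) NULL)
      if (!is.null(e))
        ens[[length(ens) + 1L]] <- c(list(stage = st, interval = iv), e)
    }
  }
  ens_df <- if (length(ens)) do.call(rbind, lapply(ens, as.data.frame))
            else NULL

  descriptors <- c("A_mm2", "P_mm", "ML_mm", "mL_mm", "SF", "EF", "CF",
                   "FDP", "FDA")
  tab1 <- group_table(frac, descriptors, within = "stage",
                      alpha = config$alpha, gate = config$gate,
                      adjust = config$adjust)
  logmsg("group table: %d rows", nrow(tab1))

  texture <- NULL
  if (config$mode == "synthetic") {
    texture <- .texture_table(config)
    logmsg("texture: %d patches", nrow(texture))
  }

  # stage-wise trend tests (Spearman rank correlation vs stage order)
  stage_order <- match(frac$stage, unique(frac$stage))
  trend <- function(v, dir) {
    ok <- !is.na(v)
    ct <- suppressWarnings(
      stats::cor.test(stage_order[ok], v[ok], method = "spearman",
                      alternative = if (dir > 0) "greater" else "less"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  trends <- rbind(
    A = trend(frac$A_mm2, +1), P = trend(frac$P_mm, +1),
    SF = trend(frac$SF, +1), EF = trend(frac$EF, -1),
    FDP = trend(frac$FDP, -1), FDA = trend(frac$FDA, +1))
  trends <- data.frame(descriptor = rownames(trends),
                       direction = c("up", "up", "up", "down", "down", "up"),
                       rho = trends[, "rho"], p = trends[, "p"],
                       row.names = NULL)

  paths <- list(
    morphometry = file.path(config$out_dir, "morphometry.csv"),
    fractal = file.path(config$out_dir, "fractal.csv"),
    table1 = file.path(config$out_dir, "table1_style.csv"),
    summary = file.path(config$out_dir, "summary.json"),
    config = file.path(config$out_dir, "effective_config.json"),
    log = logf)
  .write_csv6(morpho, paths$morphometry)
  .write_csv6(frac, paths$fractal)
  .write_csv6(tab1, paths$table1)
  if (!is.null(texture)) {
    paths$texture <- file.path(config$out_dir, "texture.csv")
    .write_csv6(texture, paths$texture)
  }

  group_means <- stats::aggregate(
    frac[descriptors], by = list(stage = frac$stage,
                                 interval = frac$interval),
    function(x) mean(x, na.rm = TRUE))
  summary_list <- list(
    mode = config$mode, seed = config$seed,
    n_grains = nrow(frac),
    group_means = group_means,
    ensemble_exponents = ens_df,
    trends = trends,
    letters = tab1[c("stage", "interval", "descriptor", "letters")],
    settings = list(gate = config$gate, alpha = config$alpha,
                    adjust = config$adjust, glcm_Ng = config$glcm_Ng,
                    glcm_offset = config$glcm_offset,
                    glcm_symmetric = config$glcm_symmetric))
  if (!is.null(texture)) {
    summary_list$texture_means <- stats::aggregate(
      texture[c("E", "ASM")],
      by = list(stage = texture$stage, region = texture$region), mean)
  }
  jsonlite::write_json(summary_list, paths$summary, auto_unbox = TRUE,
                       digits = 6, pretty = TRUE)
  cfg <- unclass(config)
  cfg$series <- unclass(cfg$series)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  logmsg("done")
  invisible(list(morphometry = morpho, fractal = frac, texture = texture,
                 table1 = tab1, ensembles = ens_df, trends = trends,
                 summary = summary_list, paths = paths))
}
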