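# Categorization, area normalization and feature assembly.
#
# Each FTIR parameter is split into low/medium/high categories by
# per-parameter thresholds; category statistics are normalized by the
# total scanned bone area (area-fraction weighting); the canonical
# per-sample infrared feature set is 4 parameters x (overall mean, SD)
# plus 4 x 3 categories x (area fraction, area-normalized mean,
# area-normalized SD) = 44 features.

ftir_params <- function() c("mmr", "cpr", "crystallinity", "xlr")
ftir_categories <- function() c("low", "med", "high")

#' Category thresholds from pooled values
#'
#' Splits the pooled values at their median (values equal to the median
#' go to the lower half); the low threshold is the lower-half mean minus
#' one lower-half SD, the high threshold the upper-half mean plus one
#' upper-half SD (sample SD, n-1; the SD of a singleton half is 0). A
#' constant vector yields low = high = that constant.
#'
#' @param values Numeric vector, length >= 4.
#' @return Named numeric `c(low, high)`.
#' @export
compute_category_thresholds <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("need at least 4 values to compute thresholds")
  med <- stats::median(values)
  lower <- values[values <= med]
  upper <- values[values > med]
  if (!length(upper)) upper <- lower  # constant (or all-median) input
  sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
  c(low = mean(lower) - sd0(lower), high = mean(upper) + sd0(upper))
}

#' Reference categorization thresholds
#'
#' The fixed per-parameter low/high cut values used when thresholds are
#' loaded rather than computed from pooled pixels: mineral-to-matrix
#' 3.580/5.230, carbonate-to-phosphate 0.008/0.010, crystallinity
#' 1.072/1.164, cross-link ratio 3.065/3.769.
#'
#' @return Named list of `c(low, high)` per FTIR parameter, class
#'   `category_thresholds`.
#' @export
table1_thresholds <- function() {
  structure(list(
    mmr           = c(low = 3.580, high = 5.230),
    cpr           = c(low = 0.008, high = 0.010),
    crystallinity = c(low = 1.072, high = 1.164),
    xlr           = c(low = 3.065, high = 3.769)
  ), class = "category_thresholds")
}

#' Thresholds pooled across a cohort's pixel tables
#'
#' Pools the valid pixels of every sample and applies
#' [compute_category_thresholds()] per FTIR parameter.
#'
#' @param pixel_tables List of pixel tables from [extract_pixel_table()].
#' @return A `category_thresholds` object.
#' @export
cohort_thresholds <- function(pixel_tables) {
  out <- lapply(ftir_params(), function(p) {
    pooled <- unlist(lapply(pixel_tables, function(tb) tb[[p]][tb$valid]))
    compute_category_thresholds(pooled)
  })
  names(out) <- ftir_params()
  structure(out, class = "category_thresholds")
}

#' Categorize values as low / medium / high
#'
#' Low iff value < low threshold (strict), high iff value > high
#' threshold (strict); everything else, boundaries included, is medium.
#'
#' @param value Numeric vector.
#' @param thresholds Named `c(low, high)` for one parameter.
#' @return Factor with levels `low`, `med`, `high`.
#' @export
categorize <- function(value, thresholds) {
  if (thresholds[["low"]] > thresholds[["high"]])
    stop("low threshold exceeds high threshold")
  out <- rep("med", length(value))
  out[value < thresholds[["low"]]] <- "low"
  out[value > thresholds[["high"]]] <- "high"
  factor(out, levels = ftir_categories())
}

#' Per-category area statistics
#'
#' For every FTIR parameter and category: pixel count, bone area (count x
#' pixel area), area fraction of the total scanned bone area, and the
#' area-normalized mean and SD (the within-category mean and sample SD
#' multiplied by the category's area fraction; the SD of an empty or
#' singleton category is 0). Only valid pixels enter. Area fractions sum
#' to 1 per parameter and category areas to the total bone area.
#'
#' @param pixel_table Output of [extract_pixel_table()].
#' @param thresholds A `category_thresholds` object.
#' @param pixel_size Pixel edge length in um (default 6).
#' @return Data.frame with one row per parameter x category.
#' @export
category_area_stats <- function(pixel_table, thresholds, pixel_size = 6) {
  tb <- pixel_table[pixel_table$valid, , drop = FALSE]
  if (nrow(tb) == 0) stop("pixel table has no valid pixels")
  px_area <- pixel_size^2
  total <- nrow(tb) * px_area
  rows <- list()
  for (p in ftir_params()) {
    cat_ <- categorize(tb[[p]], thresholds[[p]])
    for (cg in ftir_categories()) {
      v <- tb[[p]][cat_ == cg]
      n <- length(v)
      frac <- n / nrow(tb)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, category = cg, n_pixels = n,
        area_um2 = n * px_area, area_fraction = frac,
        norm_mean = if (n) mean(v) * frac else 0,
        norm_sd = if (n >= 2) stats::sd(v) * frac else 0)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "total_bone_area_um2") <- total
  out
}

#' Canonical infrared feature names
#'
#' @return Character vector of the 44 feature names, in canonical order:
#'   per parameter the overall mean and SD, then per category the area
#'   fraction, area-normalized mean and area-normalized SD.
#' @export
ir_feature_names <- function() {
  unlist(lapply(ftir_params(), function(p) {
    c(paste0(p, c("_mean", "_sd")),
      unlist(lapply(ftir_categories(), function(cg)
        paste0(p, "_", cg, c("_frac", "_nmean", "_nsd")))))
  }))
}

#' Histomorphometric modeling parameter names
#'
#' The 12 parameters of the default modeling set (ASBMR nomenclature,
#' snake_case): BV/TV, Tb.Sp, Tb.Th, OV/BV, OS/BS, O.Th, N.Ob/B.Pm,
#' ES/BS, N.Oc/B.Pm, MAR, MS/BS, Ac.f. BFR/BS and Mlt are carried in the
#' cohort table as derived extras but excluded here.
#'
#' @return Character vector of length 12.
#' @export
histo_feature_names <- function() {
  c("bv_tv", "tb_sp", "tb_th", "ov_bv", "os_bs", "o_th",
    "n_ob_bpm", "es_bs", "n_oc_bpm", "mar", "ms_bs", "ac_f")
}

#' Assemble the 44 infrared features for one sample
#'
#' @param pixel_table Output of [extract_pixel_table()].
#' @param thresholds A `category_thresholds` object.
#' @return Named numeric vector of length 44, in [ir_feature_names()]
#'   order.
#' @export
assemble_ir_features <- function(pixel_table, thresholds) {
  tb <- pixel_table[pixel_table$valid, , drop = FALSE]
  if (nrow(tb) == 0) stop("pixel table has no valid pixels")
  stats_ <- category_area_stats(pixel_table, thresholds)
  out <- numeric(0)
  for (p in ftir_params()) {
    v <- tb[[p]]
    out[paste0(p, "_mean")] <- mean(v)
    out[paste0(p, "_sd")] <- if (length(v) >= 2) stats::sd(v) else 0
    for (cg in ftir_categories()) {
      row <- stats_[stats_$parameter == p & stats_$category == cg, ]
      out[paste0(p, "_", cg, "_frac")] <- row$area_fraction
      out[paste0(p, "_", cg, "_nmean")] <- row$norm_mean
      out[paste0(p, "_", cg, "_nsd")] <- row$norm_sd
    }
  }
  stopifnot(identical(names(out), ir_feature_names()))
  out
}

#' Bind per-sample infrared features to the patient table
#'
#' @param features Named list (by patient id) of 44-feature vectors.
#' @param patients Patient table with a `patient_id` column
#'   (covariates + histomorphometry + outcomes).
#' @return Data.frame, one row per patient, patient columns followed by
#'   the 44 infrared feature columns.
#' @export
build_cohort_table <- function(features, patients) {
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient id: ",
         patients$patient_id[duplicated(patients$patient_id)][1])
  if (anyDuplicated(names(features)))
    stop("duplicate feature entry: ",
         names(features)[duplicated(names(features))][1])
  missing <- setdiff(patients$patient_id, names(features))
  if (length(missing))
    stop("missing infrared features for patient: ", missing[1])
  extra <- setdiff(names(features), patients$patient_id)
  if (length(extra))
    stop("features supplied for unknown patient: ", extra[1])
  fmat <- do.call(rbind, features[patients$patient_id])
  if (!identical(colnames(fmat), ir_feature_names()))
    stop("feature vectors do not match the canonical 44-feature layout")
  out <- cbind(patients, as.data.frame(fmat))
  if (anyNA(out[setdiff(names(out), "patient_id")]))
    stop("cohort table contains missing values after assembly")
  rownames(out) <- NULL
  out
}

#' Write / read a cohort table as CSV
#'
#' Numeric columns are written with 12 significant digits so a
#' write-read-write cycle is byte-identical.
#'
#' @param cohort Cohort table from [build_cohort_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  fmt <- cohort
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(x) sprintf("%.12g", x))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
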