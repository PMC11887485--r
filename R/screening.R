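#' Assign response categories
#'
#' Maps dopamine-normalized responses to the four screening categories:
#' group I (high, >= 1.00), group II (intermediate, 0.75-1.00), group III
#' (low, 0.15-0.50, both ends included) and group IV (no response, < 0.10).
#' Values falling in the two gaps the category definition leaves open,
#' \[0.10, 0.15) and (0.50, 0.75), are returned as `"unassigned"` rather
#' than silently extended into a neighboring bin, so the ambiguity stays
#' visible downstream.
#'
#' @param normalized Numeric vector of dopamine-normalized responses
#'   (dopamine = 1).
#' @return Factor with levels `IV < III < II < I` plus `unassigned`.
#' @examples
#' classify_response(c(1.2, 0.8, 0.3, 0.05, 0.6))
#' @export
classify_response <- function(normalized) {
  if (any(!is.finite(normalized))) {
    abort("normalized responses must be finite")
  }
  lab <- dplyr::case_when(
    normalized >= 1.00 ~ "I",
    normalized >= 0.75 ~ "II",
    normalized > 0.50 ~ "unassigned",
    normalized >= 0.15 ~ "III",
    normalized >= 0.10 ~ "unassigned",
    TRUE ~ "IV"
  )
  factor(lab, levels = c("IV", "III", "II", "I", "unassigned"))
}

#' Normalize responses to a reference analyte
#'
#' Divides each analyte's mean \eqn{\Delta F/F} by the plate-matched
#' reference (dopamine) mean, so the reference gets exactly 1.
#' [screen_plate()] also exposes a paired per-replicate ("mean of ratios")
#' convention; this function is the ratio-of-means default.
#'
#' @param records Data frame with columns `analyte_id` and `dff` (one row
#'   per analyte, mean dff).
#' @param reference_id Analyte id of the reference compound (e.g. `"DA"`).
#' @return The input with a `normalized` column added.
#' @export
normalize_to_reference <- function(records, reference_id) {
  check_columns(records, c("analyte_id", "dff"), "records")
  ref <- records$dff[records$analyte_id == reference_id]
  if (length(ref) == 0) {
    abort(sprintf("reference analyte '%s' not found", reference_id))
  }
  ref_mean <- mean(ref)
  if (!is.finite(ref_mean) || ref_mean == 0) {
    abort(sprintf("reference '%s' has zero mean dF/F; cannot normalize",
                  reference_id))
  }
  dplyr::mutate(records, normalized = .data$dff / ref_mean)
}

#' Process one screening plate into response records
#'
#' End-to-end quantification of a fluorescence screen: per-well spectra are
#' blank-subtracted (mean over blank wells at the matching timepoint),
#' integrated (full spectrum and, optionally, a chirality window), turned
#' into \eqn{\Delta F/F = (F - F_0)/F_0}, averaged over replicate wells,
#' normalized to the plate's reference analyte and categorized.
#'
#' The baseline read is the `timepoint_min == 0` row block of each well;
#' `F` is taken from the read at `timepoint` (default 30 min, the read the
#' screen is scored on).
#'
#' @param plate Long-format plate data: columns `well_id`, `timepoint_min`,
#'   `wavelength_nm`, `intensity`.
#' @param plate_map Columns `well_id`, `analyte_id`, `role` with role in
#'   `sample`, `blank`, `reference`.
#' @param reference_id Reference analyte id used for normalization
#'   (default `"DA"`, dopamine).
#' @param timepoint Read (min) used as `F`; default 30.
#' @param window Optional length-2 nm interval for the per-chirality
#'   response column `dff_peak94`.
#' @param method Normalization convention, see [normalize_to_reference()].
#' @return A tibble with one row per analyte: `analyte_id`, `F0`, `F`,
#'   `dff`, `dff_peak94`, `normalized`, `category`, `n`, `sd`.
#' @export
screen_plate <- function(plate, plate_map, reference_id = "DA",
                         timepoint = 30, window = NULL,
                         method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  check_columns(plate, c("well_id", "timepoint_min", "wavelength_nm",
                         "intensity"), "plate")
  check_columns(plate_map, c("well_id", "analyte_id", "role"), "plate_map")
  if (!any(plate_map$role == "blank")) abort("plate_map has no blank wells")
  if (!timepoint %in% plate$timepoint_min) {
    abort(sprintf("no read at timepoint %g min", timepoint))
  }

  blank_ids <- plate_map$well_id[plate_map$role == "blank"]
  blank_mean <- plate %>%
    filter(.data$well_id %in% blank_ids) %>%
    group_by(.data$timepoint_min, .data$wavelength_nm) %>%
    summarise(blank_intensity = mean(.data$intensity), .groups = "drop")

  sample_map <- plate_map[plate_map$role != "blank", ]
  wells <- plate %>%
    filter(.data$well_id %in% sample_map$well_id,
           .data$timepoint_min %in% c(0, timepoint)) %>%
    left_join(blank_mean, by = c("timepoint_min", "wavelength_nm")) %>%
    mutate(intensity = .data$intensity - .data$blank_intensity)

  spectrum_of <- function(df) {
    emission_spectrum(df$wavelength_nm[order(df$wavelength_nm)],
                      df$intensity[order(df$wavelength_nm)])
  }
  per_well <- wells %>%
    group_by(.data$well_id) %>%
    dplyr::group_modify(function(df, key) {
      s0 <- spectrum_of(df[df$timepoint_min == 0, ])
      s1 <- spectrum_of(df[df$timepoint_min == timepoint, ])
      f0 <- integrate_spectrum(s0)
      f1 <- integrate_spectrum(s1)
      tibble(
        F0 = f0, F = f1, dff = compute_dff(f0, f1),
        dff_peak94 = if (is.null(window)) NA_real_ else
          extract_peak_response(s0, s1, window)
      )
    }) %>%
    ungroup() %>%
    left_join(sample_map, by = "well_id")

  per_analyte <- per_well %>%
    group_by(.data$analyte_id) %>%
    summarise(F0 = mean(.data$F0), F = mean(.data$F),
              sd = sd(.data$dff), dff = mean(.data$dff),
              dff_peak94 = mean(.data$dff_peak94), n = dplyr::n(),
              .groups = "drop")

  if (method == "mean_of_ratios") {
    # pair replicate i of each analyte with reference replicate i
    ref_dff <- per_well$dff[per_well$analyte_id == reference_id]
    if (length(ref_dff) == 0 || mean(ref_dff) == 0) {
      abort(sprintf("reference '%s' missing or has zero mean dF/F",
                    reference_id))
    }
    norm <- per_well %>%
      group_by(.data$analyte_id) %>%
      arrange(.data$well_id, .by_group = TRUE) %>%
      mutate(.ref = ref_dff[pmin(dplyr::row_number(), length(ref_dff))]) %>%
      summarise(normalized = mean(.data$dff / .data$.ref), .groups = "drop")
    per_analyte <- left_join(per_analyte, norm, by = "analyte_id")
  } else {
    per_analyte <- normalize_to_reference(per_analyte, reference_id)
  }

  per_analyte %>%
    mutate(category = classify_response(.data$normalized)) %>%
    select("analyte_id", "F0", "F", "dff", "dff_peak94",
           "normalized", "category", "n", "sd")
}
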