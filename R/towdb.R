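TOW_HABITATS <- c("lake", "river", "marine_estuarine")

# Observed mesh-size range across published tow studies; values outside are
# flagged (not rejected) during validation.
MESH_PLAUSIBLE_UM <- c(45, 780)

#' Sample volume of a net tow
#'
#' Volume filtered by a circular plankton net towed horizontally: mouth area
#' times tow distance.  A 300-mm net towed 100 m filters 7,068.6 L, reported
#' as 7,100 L at two significant figures.
#'
#' @param mouth_diameter_m net mouth diameter in metres.
#' @param tow_distance_m tow distance in metres (0 allowed).
#' @param submerged_frac fraction of the mouth area below the surface
#'   (default 1: fully submerged).
#' @param signif_digits if not `NULL`, round the result to this many
#'   significant figures.
#' @return volume in litres.
#' @export
compute_sample_volume <- function(mouth_diameter_m, tow_distance_m,
                                  submerged_frac = 1, signif_digits = NULL) {
  if (any(mouth_diameter_m <= 0)) stop("mouth diameter must be positive")
  if (any(tow_distance_m < 0)) stop("tow distance must be non-negative")
  stopifnot(submerged_frac > 0, submerged_frac <= 1)
  vol_l <- pi * (mouth_diameter_m / 2)^2 * submerged_frac *
    tow_distance_m * 1000
  if (!is.null(signif_digits)) vol_l <- signif(vol_l, signif_digits)
  vol_l
}

#' Convert an areal concentration to a volumetric one
#'
#' A transect of width equal to the net mouth diameter sweeps
#' `d * distance` of surface while filtering `area * distance` of water, so
#' `C_V = C_A * 4 / (f * pi * d)` with `C_A` in particles per square metre
#' and `f` the submerged fraction of the circular mouth.
#'
#' @param concentration_per_km2 areal concentration, particles km^-2.
#' @param mouth_diameter_m net mouth diameter in metres.
#' @param submerged_frac submerged fraction of the mouth (default 1).
#' @return volumetric concentration, particles m^-3.
#' @export
areal_to_volumetric <- function(concentration_per_km2, mouth_diameter_m,
                                submerged_frac = 1) {
  if (any(mouth_diameter_m <= 0)) stop("mouth diameter must be positive")
  conc_m2 <- concentration_per_km2 / 1e6
  conc_m2 * 4 / (submerged_frac * pi * mouth_diameter_m)
}

#' Detection limit of a tow
#'
#' One particle per filtered volume: the smallest nonzero concentration a tow
#' can record.  Zero counts are censored below this limit in the global
#' model.
#'
#' @param volume_m3 filtered volume, cubic metres.
#' @return particles m^-3.
#' @export
detection_limit <- function(volume_m3) {
  if (any(volume_m3 <= 0)) stop("volume must be positive")
  1 / volume_m3
}

RELIABILITY_ITEMS <- c(reproducible_sampling = 2,
                       volume_over_500L = 2,
                       precombusted_storage = 2,
                       lab_contamination_mitigation = 2,
                       airborne_mitigation_controls = 1,
                       negative_controls = 1,
                       polymer_id_subset = 1)

#' Methods-reliability checklist
#'
#' @param reproducible_sampling,volume_over_500L,precombusted_storage,lab_contamination_mitigation,airborne_mitigation_controls,negative_controls,polymer_id_subset
#'   logical flags for the seven rubric items.
#' @return named logical vector of class `reliability_checklist`.
#' @export
reliability_checklist <- function(reproducible_sampling = FALSE,
                                  volume_over_500L = FALSE,
                                  precombusted_storage = FALSE,
                                  lab_contamination_mitigation = FALSE,
                                  airborne_mitigation_controls = FALSE,
                                  negative_controls = FALSE,
                                  polymer_id_subset = FALSE) {
  x <- c(reproducible_sampling = reproducible_sampling,
         volume_over_500L = volume_over_500L,
         precombusted_storage = precombusted_storage,
         lab_contamination_mitigation = lab_contamination_mitigation,
         airborne_mitigation_controls = airborne_mitigation_controls,
         negative_controls = negative_controls,
         polymer_id_subset = polymer_id_subset)
  if (!is.logical(x) || anyNA(x)) stop("all checklist items must be TRUE/FALSE")
  structure(x, class = "reliability_checklist")
}

#' Methods-reliability score
#'
#' Weighted sum of the seven rubric items with weights (2, 2, 2, 2, 1, 1, 1):
#' reproducible sampling, >=500 L trawled, precombusted storage, laboratory
#' contamination mitigation (2 points each); airborne mitigation with
#' parallel controls, negative controls, polymer identification of a subset
#' (1 point each).  A study meeting every item scores 11.
#'
#' @param checklist a [reliability_checklist()] or named logical vector
#'   covering all seven items.
#' @return numeric score in `[0, 11]`.
#' @export
reliability_score <- function(checklist) {
  items <- names(RELIABILITY_ITEMS)
  if (!all(items %in% names(checklist)))
    stop("checklist is missing items: ",
         paste(setdiff(items, names(checklist)), collapse = ", "))
  vals <- as.logical(checklist[items])
  if (anyNA(vals)) stop("checklist items must be TRUE/FALSE")
  sum(RELIABILITY_ITEMS * vals)
}

TOWDB_COLUMNS <- c("study_id", "habitat", "mesh_size_um",
                   "net_mouth_diameter_m", "tow_distance_m", "volume_m3",
                   "concentration_per_m3", "detection_limit_per_m3",
                   "lake_area_km2", "latitude_deg")

#' Read and validate a net-tow database
#'
#' Accepts tab-, comma- or semicolon-delimited text with a header row.
#' Decimal commas are normalised when the delimiter is not a comma;
#' unparseable numeric cells become `NA`, never 0.  Rows with an unknown
#' habitat label are dropped and reported.  If the file carries an areal
#' `concentration_per_km2` column but no volumetric one, rows with known
#' mouth geometry are converted with [areal_to_volumetric()]; rows without
#' geometry are flagged, not converted.  Missing detection limits default to
#' one particle per tow volume (overridable per record in the file).
#'
#' @param path input file.
#' @return data frame of validated records; validation messages are attached
#'   as a data frame in `attr(, "problems")` (columns `row`, `field`,
#'   `message`), and mesh sizes outside the plausible 45-780 um window are
#'   flagged in the logical column `mesh_flagged`.
#' @export
read_towdb <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           colClasses = "character", check.names = TRUE,
                           comment.char = "")
  num <- function(x) {
    if (sep != ",") x <- sub("^(-?[0-9]+),([0-9]+)$", "\\1.\\2", x)
    suppressWarnings(as.numeric(x))
  }
  problems <- data.frame(row = integer(), field = character(),
                         message = character(), stringsAsFactors = FALSE)
  note <- function(row, field, msg) {
    problems <<- rbind(problems, data.frame(row = row, field = field,
                                            message = msg,
                                            stringsAsFactors = FALSE))
  }

  n <- nrow(raw)
  db <- data.frame(
    study_id = as.character(raw$study_id %||% rep(NA_character_, n)),
    habitat = as.character(raw$habitat %||% rep(NA_character_, n)),
    mesh_size_um = num(raw$mesh_size_um %||% rep(NA, n)),
    net_mouth_diameter_m = num(raw$net_mouth_diameter_m %||% rep(NA, n)),
    tow_distance_m = num(raw$tow_distance_m %||% rep(NA, n)),
    volume_m3 = num(raw$volume_m3 %||% rep(NA, n)),
    concentration_per_m3 = num(raw$concentration_per_m3 %||% rep(NA, n)),
    detection_limit_per_m3 = num(raw$detection_limit_per_m3 %||% rep(NA, n)),
    lake_area_km2 = num(raw$lake_area_km2 %||% rep(NA, n)),
    latitude_deg = num(raw$latitude_deg %||% rep(NA, n)),
    stringsAsFactors = FALSE)

  # volumes from geometry where absent
  need_vol <- is.na(db$volume_m3) & !is.na(db$net_mouth_diameter_m) &
    !is.na(db$tow_distance_m)
  db$volume_m3[need_vol] <- compute_sample_volume(
    db$net_mouth_diameter_m[need_vol], db$tow_distance_m[need_vol]) / 1000

  # areal-to-volumetric conversion
  if (!is.null(raw$concentration_per_km2)) {
    areal <- num(raw$concentration_per_km2)
    conv <- is.na(db$concentration_per_m3) & !is.na(areal)
    has_geom <- !is.na(db$net_mouth_diameter_m)
    db$concentration_per_m3[conv & has_geom] <- areal_to_volumetric(
      areal[conv & has_geom], db$net_mouth_diameter_m[conv & has_geom])
    for (i in which(conv & !has_geom))
      note(i, "concentration_per_km2",
           "areal record without mouth geometry; not converted")
  }

  drop <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (is.na(db$habitat[i]) || !(db$habitat[i] %in% TOW_HABITATS)) {
      note(i, "habitat", sprintf(
        "unknown habitat '%s' (expected %s)", db$habitat[i],
        paste(TOW_HABITATS, collapse = "/")))
      drop[i] <- TRUE
    }
    if (!is.na(db$volume_m3[i]) && db$volume_m3[i] <= 0) {
      note(i, "volume_m3", "volume must be positive")
      drop[i] <- TRUE
    }
    if (!is.na(db$concentration_per_m3[i]) && db$concentration_per_m3[i] < 0) {
      note(i, "concentration_per_m3", "negative concentration")
      drop[i] <- TRUE
    }
    if (is.na(db$mesh_size_um[i]))
      note(i, "mesh_size_um", "missing or non-numeric mesh size")
  }
  db <- db[!drop, , drop = FALSE]
  rownames(db) <- NULL

  fill_dl <- is.na(db$detection_limit_per_m3) & !is.na(db$volume_m3)
  db$detection_limit_per_m3[fill_dl] <- detection_limit(db$volume_m3[fill_dl])
  db$mesh_flagged <- !is.na(db$mesh_size_um) &
    (db$mesh_size_um < MESH_PLAUSIBLE_UM[1] |
       db$mesh_size_um > MESH_PLAUSIBLE_UM[2])

  attr(db, "problems") <- problems
  db
}

#' Write a net-tow database as tab-delimited text
#'
#' Round-trips losslessly through [read_towdb()].
#'
#' @param db data frame of tow records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_towdb <- function(db, path) {
  cols <- intersect(c(TOWDB_COLUMNS, "mesh_flagged"), names(db))
  utils::write.table(db[cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
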