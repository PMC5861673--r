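#' Leaf sample
#'
#' One measured leaf: identifiers, its white-background reflectance
#' spectrum, and the destructive reference contents of exactly one subset
#' (pigment leaves carry `Cab`/`Cc`, water/dry-matter leaves carry
#' `Cw`/`Cm`), reflecting the destructive sampling design in which separate
#' leaves are used for pigment extraction and for weighing.
#'
#' @param leaf_id Leaf identifier.
#' @param spectrum A [spectrum()].
#' @param destructive Named list: either `list(Cab=, Cc=)` or
#'   `list(Cw=, Cm=)`, values `>= 0`; may be `NULL` for undetermined leaves.
#' @param sample_id,stage,cultivar,modality Optional metadata (stage is
#'   `"two_nodes_april"` or `"grain_filling_june"`).
#' @return An object of class `leaf_sample` with a `subset` field
#'   (`"pigment"`, `"water"` or `NA`).
#' @export
leaf_sample <- function(leaf_id, spectrum, destructive = NULL,
                        sample_id = NA, stage = NA, cultivar = NA,
                        modality = NA) {
  stopifnot(inherits(spectrum, "leaf_spectrum"))
  subset <- NA_character_
  if (!is.null(destructive)) {
    nm <- sort(names(destructive))
    if (identical(nm, c("Cab", "Cc"))) subset <- "pigment"
    else if (identical(nm, c("Cm", "Cw"))) subset <- "water"
    else stop("destructive contents must be {Cab, Cc} or {Cw, Cm}")
    if (any(unlist(destructive) < 0))
      stop("destructive contents must be >= 0")
  }
  structure(list(leaf_id = leaf_id, sample_id = sample_id, stage = stage,
                 cultivar = cultivar, modality = modality,
                 spectrum = spectrum, destructive = destructive,
                 subset = subset),
            class = "leaf_sample")
}

#' @export
print.leaf_sample <- function(x, ...) {
  cat(sprintf("<leaf_sample> %s (%s subset)\n", x$leaf_id,
              if (is.na(x$subset)) "no destructive" else x$subset))
  print(x$spectrum)
  invisible(x)
}

#' Destructive water and dry-matter contents
#'
#' `Cm = M_dry / S` and `Cw = (M_fresh - M_dry) / S`, from the fresh and
#' oven-dry masses and the measured leaf area.
#'
#' @param m_fresh,m_dry Fresh and dry mass (mg), `m_fresh >= m_dry >= 0`.
#' @param area Leaf area (cm2), `> 0`.
#' @return A list with `Cw` and `Cm` in mg/cm2.
#' @export
destructive_contents <- function(m_fresh, m_dry, area) {
  if (any(area <= 0)) stop("leaf area must be > 0")
  if (any(m_dry < 0)) stop("dry mass must be >= 0")
  if (any(m_fresh < m_dry))
    stop("fresh mass below dry mass: negative water content")
  list(Cw = (m_fresh - m_dry) / area, Cm = m_dry / area)
}

#' Reflectance factor from raw instrument signals
#'
#' Converts the averaged raw leaf signal into a directional-hemispherical
#' reflectance factor using the secondary white reference measured before
#' and after the acquisition series:
#' \deqn{DHRF_{leaf}(\lambda) = \frac{2 S_{leaf}(\lambda)}
#'   {S_{ref,bef}(\lambda) + S_{ref,aft}(\lambda)} DHRF_{ref}(\lambda)}
#' Values above 1.05 are reported with a warning and clipped.
#'
#' @param s_leaf,s_ref_before,s_ref_after Raw signal spectra
#'   (`calibrated = FALSE`) on a common grid; reference signals must be
#'   strictly positive.
#' @param dhrf_ref Calibrated reflectance factor of the secondary
#'   reference.
#' @return A calibrated `leaf_spectrum`.
#' @export
dhrf_from_signals <- function(s_leaf, s_ref_before, s_ref_after, dhrf_ref) {
  specs <- list(s_leaf, s_ref_before, s_ref_after, dhrf_ref)
  wl <- s_leaf$wavelength
  for (s in specs) {
    stopifnot(inherits(s, "leaf_spectrum"))
    if (length(s$wavelength) != length(wl) || any(s$wavelength != wl))
      stop("signal spectra are not on a common grid")
  }
  if (any(s_ref_before$value <= 0) || any(s_ref_after$value <= 0))
    stop("zero or negative reference signal")
  refsum <- s_ref_before$value + s_ref_after$value
  v <- 2 * s_leaf$value / refsum * dhrf_ref$value
  if (any(v > 1.05)) {
    warning(sum(v > 1.05), " wavelengths above 1.05 were clipped")
    v <- pmin(v, 1.05)
  }
  if (any(v < 0)) v <- pmax(v, 0)
  spectrum(wl, v, calibrated = TRUE)
}

.default_id_cols <- c(leaf_id = "leaf_id", sample_id = "sample_id",
                      stage = "stage", cultivar = "cultivar",
                      modality = "modality")

# parse one wide sheet (one row per leaf, R_<nm> spectral columns)
.parse_sheet <- function(d, subset, grid, sheet_name) {
  wlcols <- grep("^R_\\d+(\\.\\d+)?$", names(d), value = TRUE)
  if (length(wlcols) < 2)
    stop("sheet '", sheet_name, "': no R_<wavelength> spectral columns")
  wl <- as.numeric(sub("^R_", "", wlcols))
  o <- order(wl)
  if (any(diff(wl[o]) <= 0))
    stop("sheet '", sheet_name, "': duplicated wavelength columns")
  wl <- wl[o]; wlcols <- wlcols[o]
  dest_cols <- if (subset == "pigment") c("Cab", "Cc") else c("Cw", "Cm")
  samples <- list()
  skipped <- character()
  for (i in seq_len(nrow(d))) {
    vals <- suppressWarnings(as.numeric(d[i, wlcols]))
    id <- if ("leaf_id" %in% names(d)) as.character(d$leaf_id[i]) else
      paste0(sheet_name, "_", i)
    sp <- tryCatch({
      s <- spectrum(wl, vals)
      resample_to_grid(s, grid)
    }, error = function(e) conditionMessage(e))
    if (is.character(sp)) {
      skipped[id] <- sp
      next
    }
    dest <- NULL
    if (all(dest_cols %in% names(d))) {
      dv <- lapply(dest_cols, function(cn) as.numeric(d[i, cn]))
      names(dv) <- dest_cols
      if (!anyNA(unlist(dv))) dest <- dv
    }
    meta <- lapply(names(.default_id_cols), function(cn)
      if (cn %in% names(d)) d[i, cn] else NA)
    names(meta) <- names(.default_id_cols)
    samples[[id]] <- leaf_sample(id, sp, dest,
                                 sample_id = meta$sample_id,
                                 stage = meta$stage,
                                 cultivar = meta$cultivar,
                                 modality = meta$modality)
  }
  if (length(skipped))
    warning("sheet '", sheet_name, "': skipped ", length(skipped),
            " corrupted spectra (", paste(utils::head(names(skipped), 3),
                                          collapse = ", "), " ...)")
  samples
}

#' Read a leaf dataset
#'
#' Reads the tabular study layout: a pigment sheet (`reflectance_Chl`) with
#' leaf reflectance plus destructive `Cab`/`Cc`, a water/dry-matter sheet
#' (`reflectance_Cw_Cm`) with reflectance plus `Cw`/`Cm`, and a white
#' background sheet. Two containers are supported: a directory holding the
#' CSV bundle (`reflectance_Chl.csv`, `reflectance_Cw_Cm.csv`,
#' `white_background.csv`, optional `description.csv`) or an `.xlsx`
#' workbook with equivalently named sheets (requires the readxl package).
#' Reflectance sheets are wide: one row per leaf, metadata and destructive
#' columns, then `R_<wavelength>` columns. Corrupted spectra are skipped
#' with a warning. All spectra are resampled to `grid`.
#'
#' @param path Directory of the CSV bundle or path to an `.xlsx` file.
#' @param grid A [working_grid()].
#' @return A list with `samples` (named list of [leaf_sample()], pigment
#'   subset first) and `background` (a `leaf_spectrum`).
#' @export
read_leaf_dataset <- function(path, grid = working_grid()) {
  if (dir.exists(path)) {
    need <- file.path(path, c("reflectance_Chl.csv",
                              "reflectance_Cw_Cm.csv",
                              "white_background.csv"))
    missing <- need[!file.exists(need)]
    if (length(missing))
      stop("missing dataset file(s): ", paste(basename(missing),
                                              collapse = ", "))
    chl <- utils::read.csv(need[1], check.names = FALSE)
    wcm <- utils::read.csv(need[2], check.names = FALSE)
    wbg <- utils::read.csv(need[3])
  } else if (grepl("\\.xlsx?$", path)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package; ",
           "use the CSV bundle layout instead")
    if (!file.exists(path)) stop("no such file: ", path)
    chl <- as.data.frame(readxl::read_excel(path, sheet = "reflectance_Chl"))
    wcm <- as.data.frame(readxl::read_excel(path,
                                            sheet = "reflectance_Cw_Cm"))
    wbg <- as.data.frame(readxl::read_excel(
      path, sheet = "reflectance of white background"))
  } else {
    stop("no such dataset directory or workbook: ", path)
  }
  if (any(diff(wbg[[1]]) <= 0))
    stop("background wavelength column not strictly increasing")
  background <- resample_to_grid(spectrum(wbg[[1]], wbg[[2]]), grid)
  samples <- c(.parse_sheet(chl, "pigment", grid, "reflectance_Chl"),
               .parse_sheet(wcm, "water", grid, "reflectance_Cw_Cm"))
  list(samples = samples, background = background)
}

#' Write a leaf dataset as a CSV bundle
#'
#' Inverse of [read_leaf_dataset()] (directory layout): full-precision
#' round trip of spectra, destructive contents and metadata.
#'
#' @param samples List of [leaf_sample()] objects.
#' @param background Background `leaf_spectrum`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_leaf_dataset <- function(samples, background, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- function(subset) {
    sel <- Filter(function(s) identical(s$subset, subset), samples)
    if (!length(sel)) return(NULL)
    rows <- lapply(sel, function(s) {
      sp <- s$spectrum
      spcols <- stats::setNames(as.list(sp$value),
                                paste0("R_", sp$wavelength))
      c(list(leaf_id = s$leaf_id, sample_id = s$sample_id, stage = s$stage,
             cultivar = s$cultivar, modality = s$modality),
        s$destructive, spcols)
    })
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, check.names = FALSE)))
  }
  chl <- sheet("pigment")
  wcm <- sheet("water")
  if (!is.null(chl))
    utils::write.csv(chl, file.path(dir, "reflectance_Chl.csv"),
                     row.names = FALSE)
  if (!is.null(wcm))
    utils::write.csv(wcm, file.path(dir, "reflectance_Cw_Cm.csv"),
                     row.names = FALSE)
  utils::write.csv(
    data.frame(wavelength_nm = background$wavelength,
               reflectance = background$value),
    file.path(dir, "white_background.csv"), row.names = FALSE)
  invisible(dir)
}
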