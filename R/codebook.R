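#' Combinatorial fluorescent barcode codebook
#'
#' A codebook maps treatment conditions to dye-level vectors. Each dye has a
#' concentration ladder (umol/L, in the library droplet, descending) and each
#' code picks one level per dye, 0 meaning "dye absent". Levels are separated
#' by at least 2-fold so they stay apart in log space after imaging.
#'
#' @param codes data frame with columns `condition_label`, `drug`, `dose_umol`
#'   (drug concentration in the library droplet; 0 for vehicle controls) and
#'   one `<dye>_level` integer column per dye (0 = absent, 1 = first ladder
#'   entry, ...).
#' @param levels named list of per-dye concentration ladders (umol/L),
#'   descending.
#' @param dyes named character vector mapping channel names to dye products.
#' @param dilution_factor ratio by which library concentrations are divided on
#'   droplet merging; the exact factor (v1+v2)/v2 of the default
#'   [droplet_spec()] unless overridden.
#' @return an object of class `barcode_codebook`.
#' @export
barcode_codebook <- function(codes, levels,
                             dyes = c(red = "CF647", green = "CF488A",
                                      blue = "CF350"),
                             dilution_factor =
                               merge_dilution(droplet_spec())$exact_factor) {
  cb <- structure(list(dyes = dyes, levels = levels, codes = codes,
                       dilution_factor = dilution_factor),
                  class = "barcode_codebook")
  validate_codebook(cb)
  cb
}

#' The default 10-condition codebook
#'
#' Ten barcodes built from three dyes, mirroring the one-dye-per-drug design:
#' four red-only codes (CF647 ladder 20.0/2.5/0.32/0.04 umol/L) carrying the
#' tamoxifen dose ladder 250/30/4/0.5 umol/L, four green-only codes (CF488A,
#' same dye ladder) carrying alpelisib 63/8/1/0.1 umol/L, and two blue-only
#' codes (CF350 at 300 and 50 umol/L) for DMSO vehicle controls. Higher dye
#' level encodes higher dose.
#'
#' @param conditions optional character vector of condition labels to keep
#'   (subset constructor); e.g. a 5-condition book for a second screen.
#' @inheritParams barcode_codebook
#' @return a `barcode_codebook` with 10 codes (or `length(conditions)`).
#' @examples
#' cb <- default_codebook()
#' nrow(cb$codes)
#' @export
default_codebook <- function(conditions = NULL,
                             dilution_factor =
                               merge_dilution(droplet_spec())$exact_factor) {
  levels <- list(red = c(20.0, 2.5, 0.32, 0.04),
                 green = c(20.0, 2.5, 0.32, 0.04),
                 blue = c(300, 50))
  codes <- data.frame(
    condition_label = c(paste0("tamoxifen_", c(250, 30, 4, 0.5)),
                        paste0("alpelisib_", c(63, 8, 1, 0.1)),
                        "dmso_a", "dmso_b"),
    drug = c(rep("tamoxifen", 4), rep("alpelisib", 4), rep("dmso", 2)),
    dose_umol = c(250, 30, 4, 0.5, 63, 8, 1, 0.1, 0, 0),
    red_level = c(1:4, rep(0L, 6)),
    green_level = c(rep(0L, 4), 1:4, 0L, 0L),
    blue_level = c(rep(0L, 8), 1L, 2L)
  )
  cb <- barcode_codebook(codes, levels, dilution_factor = dilution_factor)
  if (!is.null(conditions)) cb <- subset_codebook(cb, conditions)
  cb
}

#' Keep a subset of codebook conditions
#'
#' @param cb a `barcode_codebook`.
#' @param conditions character vector of condition labels to keep, or a single
#'   integer n to keep the first n codes.
#' @return the subset `barcode_codebook`.
#' @export
subset_codebook <- function(cb, conditions) {
  stopifnot(inherits(cb, "barcode_codebook"))
  if (is.numeric(conditions) && length(conditions) == 1L) {
    keep <- seq_len(conditions)
  } else {
    keep <- match(conditions, cb$codes$condition_label)
    if (anyNA(keep)) {
      stop("unknown condition label(s): ",
           paste(conditions[is.na(keep)], collapse = ", "))
    }
  }
  cb$codes <- cb$codes[keep, , drop = FALSE]
  rownames(cb$codes) <- NULL
  validate_codebook(cb)
  cb
}

#' Validate a barcode codebook
#'
#' Invariants: all level vectors distinct; successive ladder entries at least
#' 2-fold apart (log-separability); number of codes at most
#' `prod(levels + 1) - 1` (the all-absent word is reserved for "no barcode").
#'
#' @param cb a `barcode_codebook`.
#' @return the codebook, invisibly. Errors on violation.
#' @export
validate_codebook <- function(cb) {
  stopifnot(inherits(cb, "barcode_codebook"))
  lv_cols <- paste0(names(cb$dyes), "_level")
  if (!all(lv_cols %in% names(cb$codes))) {
    stop("codes must have a <dye>_level column for every dye")
  }
  key <- apply(cb$codes[lv_cols], 1L, paste, collapse = "/")
  if (anyDuplicated(key)) stop("codebook codes are not distinct")
  if (any(key == paste(rep(0, length(lv_cols)), collapse = "/"))) {
    stop("the all-absent dye word cannot be a code (reserved for 'no barcode')")
  }
  for (dye in names(cb$dyes)) {
    lad <- cb$levels[[dye]]
    if (is.null(lad) || any(lad <= 0) || is.unsorted(rev(lad), strictly = TRUE)) {
      stop("ladder for dye '", dye, "' must be positive and strictly descending")
    }
    if (length(lad) > 1L && any(lad[-length(lad)] / lad[-1L] < 2)) {
      stop("ladder for dye '", dye, "' has successive levels closer than 2-fold")
    }
    if (any(cb$codes[[paste0(dye, "_level")]] > length(lad))) {
      stop("code refers to a level beyond the '", dye, "' ladder")
    }
  }
  max_codes <- prod(lengths(cb$levels) + 1) - 1
  if (nrow(cb$codes) > max_codes) {
    stop("more codes than representable dye-level combinations")
  }
  invisible(cb)
}

#' @export
print.barcode_codebook <- function(x, ...) {
  cat(sprintf("barcode_codebook: %d codes, dyes %s, dilution factor %.3f\n",
              nrow(x$codes),
              paste(sprintf("%s=%s", names(x$dyes), x$dyes), collapse = " "),
              x$dilution_factor))
  invisible(x)
}

#' Per-code library dye concentrations
#'
#' Expands level indices into umol/L concentrations (library scale; divide by
#' `cb$dilution_factor` for the post-merge scale).
#'
#' @param cb a `barcode_codebook`.
#' @return data frame `condition_label` + one `<dye>_umol` column per dye.
#' @export
code_concentrations <- function(cb) {
  stopifnot(inherits(cb, "barcode_codebook"))
  out <- data.frame(condition_label = cb$codes$condition_label)
  for (dye in names(cb$dyes)) {
    lv <- cb$codes[[paste0(dye, "_level")]]
    out[[paste0(dye, "_umol")]] <- ifelse(lv == 0, 0, cb$levels[[dye]][pmax(lv, 1L)])
  }
  out
}

#' Write / read a codebook as CSV
#'
#' Format: `condition_label, drug, dose_umol, red_umol, green_umol, blue_umol`
#' with library-scale concentrations (0 = dye absent). Ladders are recovered as
#' the sorted distinct nonzero concentrations per dye.
#'
#' @param cb a `barcode_codebook`.
#' @param path CSV file path.
#' @param dilution_factor used when reading (not stored in the CSV).
#' @return `write_codebook_csv`: the path, invisibly; `read_codebook_csv`: a
#'   `barcode_codebook`.
#' @export
write_codebook_csv <- function(cb, path) {
  conc <- code_concentrations(cb)
  out <- cbind(cb$codes[c("condition_label", "drug", "dose_umol")],
               conc[-1L])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_codebook_csv
#' @export
read_codebook_csv <- function(path,
                              dilution_factor =
                                merge_dilution(droplet_spec())$exact_factor) {
  df <- utils::read.csv(path)
  dye_cols <- grep("_umol$", names(df), value = TRUE)
  dye_cols <- setdiff(dye_cols, "dose_umol")
  dyes <- sub("_umol$", "", dye_cols)
  levels <- lapply(dye_cols, function(cc) {
    sort(unique(df[[cc]][df[[cc]] > 0]), decreasing = TRUE)
  })
  names(levels) <- dyes
  codes <- df[c("condition_label", "drug", "dose_umol")]
  for (dye in dyes) {
    conc <- df[[paste0(dye, "_umol")]]
    codes[[paste0(dye, "_level")]] <-
      ifelse(conc == 0, 0L, match(conc, levels[[dye]]))
  }
  dye_names <- c(red = "CF647", green = "CF488A", blue = "CF350")[dyes]
  dye_names[is.na(dye_names)] <- "unknown"
  names(dye_names) <- dyes
  barcode_codebook(codes, levels, dyes = dye_names,
                   dilution_factor = dilution_factor)
}
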