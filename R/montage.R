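# 19-channel 10-20 montage on a schematic integer grid.
#
# The grid is the conventional schematic layout of the clinical 19-electrode
# montage: columns -2..2 (negative = left hemisphere), rows 2 (frontal-polar)
# down to -2 (occipital). Midline electrodes sit at x = 0. All electrode-pair
# distance rules used by the connectivity summaries are defined on this grid:
# pairs closer than 2 are "neighbor" (dominated by volume conduction and
# excluded from range comparisons), pairs with 2 <= d < 3 are "short" range,
# and pairs with d >= 3 are "long" range (3 is 75% of the maximum aligned
# inter-electrode distance of 4, e.g. T3-T4).

MONTAGE_NAMES <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                   "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

# Modern 10-10 synonyms accepted at input time.
ELECTRODE_ALIASES <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Build the standard 19-electrode 10-20 montage
#'
#' Returns the fixed 19-channel clinical montage as a geometric object: each
#' electrode has a signed integer grid position (negative x = left hemisphere,
#' x = 0 midline) and every one of the 171 unordered electrode pairs is
#' classified by grid Euclidean distance into `neighbor` (d < 2), `short`
#' (2 <= d < 3) or `long` (d >= 3), and flagged as homologous
#' inter-hemispheric (left/right mirror images, e.g. C3-C4) and/or
#' intra-hemispheric non-midline.
#'
#' @return An object of class `electrode_montage`: a list with
#'   `electrodes` (data frame: `name`, `grid_x`, `grid_y`, `hemisphere`) and
#'   `pairs` (data frame with one row per unordered pair: `a`, `b`,
#'   `distance`, `class`, `homologous_interhemispheric`, `intra_nonmidline`).
#' @examples
#' m <- build_standard_montage()
#' nrow(m$pairs)                       # 171
#' classify_pair(m, "T3", "T4")$class  # "long"
#' @export
build_standard_montage <- function() {
  el <- data.frame(
    name = MONTAGE_NAMES,
    grid_x = c(-1L, 1L, -2L, -1L, 0L, 1L, 2L, -2L, -1L, 0L, 1L, 2L,
               -2L, -1L, 0L, 1L, 2L, -1L, 1L),
    grid_y = c(2L, 2L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L,
               -1L, -1L, -1L, -1L, -1L, -2L, -2L),
    stringsAsFactors = FALSE
  )
  el$hemisphere <- ifelse(el$grid_x < 0, "left",
                          ifelse(el$grid_x > 0, "right", "midline"))

  idx <- utils::combn(nrow(el), 2)
  i <- idx[1, ]; j <- idx[2, ]
  d <- sqrt((el$grid_x[i] - el$grid_x[j])^2 + (el$grid_y[i] - el$grid_y[j])^2)
  pairs <- data.frame(
    a = el$name[i],
    b = el$name[j],
    distance = d,
    class = ifelse(d < 2, "neighbor", ifelse(d < 3, "short", "long")),
    homologous_interhemispheric =
      el$grid_x[i] == -el$grid_x[j] & el$grid_x[i] != 0L &
      el$grid_y[i] == el$grid_y[j],
    intra_nonmidline =
      el$hemisphere[i] == el$hemisphere[j] & el$hemisphere[i] != "midline",
    stringsAsFactors = FALSE
  )
  structure(list(electrodes = el, pairs = pairs), class = "electrode_montage")
}

#' Canonicalize electrode labels
#'
#' Trims whitespace, fixes case, and maps the modern 10-10 synonyms
#' T7/T8/P7/P8 to the clinical labels T3/T4/T5/T6.
#'
#' @param x Character vector of electrode labels.
#' @return Character vector of canonical 10-20 labels (unknown labels are
#'   returned case-normalized but unmapped).
#' @export
canonical_labels <- function(x) {
  x <- trimws(as.character(x))
  canon <- MONTAGE_NAMES[match(toupper(x), toupper(MONTAGE_NAMES))]
  x[!is.na(canon)] <- canon[!is.na(canon)]
  ali <- ELECTRODE_ALIASES[match(toupper(x), names(ELECTRODE_ALIASES))]
  x[!is.na(ali)] <- ali[!is.na(ali)]
  x
}

#' Classify one electrode pair
#'
#' Looks up the grid-distance class and pair flags for a single unordered
#' electrode pair. Classification is symmetric in `a` and `b`.
#'
#' @param montage An `electrode_montage` from [build_standard_montage()].
#' @param a,b Electrode names (10-10 aliases accepted).
#' @return One-row data frame with `a`, `b`, `distance`, `class`,
#'   `homologous_interhemispheric`, `intra_nonmidline`.
#' @export
classify_pair <- function(montage, a, b) {
  stopifnot(inherits(montage, "electrode_montage"))
  a <- canonical_labels(a); b <- canonical_labels(b)
  known <- montage$electrodes$name
  bad <- setdiff(c(a, b), known)
  if (length(bad) > 0)
    stop("unknown electrode name(s): ", paste(bad, collapse = ", "))
  if (a == b) stop("a pair requires two distinct electrodes")
  p <- montage$pairs
  hit <- (p$a == a & p$b == b) | (p$a == b & p$b == a)
  row <- p[hit, , drop = FALSE]
  rownames(row) <- NULL
  row
}

#' Export the montage as a plain-text table
#'
#' Writes the electrode table (name, grid coordinates, hemisphere) as
#' tab-separated text for audit.
#'
#' @param montage An `electrode_montage`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_montage_table <- function(montage, path) {
  stopifnot(inherits(montage, "electrode_montage"))
  utils::write.table(montage$electrodes, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat("19-electrode 10-20 montage:", nrow(x$pairs), "unordered pairs\n")
  cat("  pair classes:", paste(sprintf("%s=%d", names(table(x$pairs$class)),
                                       table(x$pairs$class)), collapse = ", "), "\n")
  invisible(x)
}

# Index of an electrode name within the montage order (after aliasing).
montage_index <- function(montage, names) {
  idx <- match(canonical_labels(names), montage$electrodes$name)
  if (anyNA(idx))
    stop("unknown electrode name(s): ",
         paste(names[is.na(idx)], collapse = ", "))
  idx
}
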