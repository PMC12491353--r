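#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join bind_rows bind_cols n distinct pull rename count
#' @importFrom stats median setNames
NULL

# round half away from zero (round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# normalize locus / column names for matching: "Y-GATA-H4" -> "YGATAH4"
norm_name <- function(x) {
  toupper(gsub("[^A-Za-z0-9]", "", x))
}

has_fraction <- function(x, tol = 1e-9) {
  !is.na(x) & abs(x - round(x)) > tol
}

# sum of squared haplotype distances helper: symmetric matrix checks
check_square_sym <- function(D, arg = "D") {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    abort(sprintf("`%s` must be a square matrix", arg))
  }
  if (max(abs(D - t(D))) > 1e-8) {
    abort(sprintf("`%s` must be symmetric", arg))
  }
  invisible(D)
}
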