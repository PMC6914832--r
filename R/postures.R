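#' Static upper-limb postures
#'
#' A static posture (SP) is encoded as a 3-letter code over
#' shoulder x elbow x wrist: the shoulder and elbow joints are either
#' flexed (`F`) or extended (`E`), and the wrist (forearm) is either
#' pronated (`P`) or supinated (`S`). For example `"FFS"` means shoulder
#' flexed, elbow flexed, wrist supinated. Exactly eight distinct postures
#' exist; each is mapped to one corner of the normalized virtual cube.
#'
#' `all_postures()` returns the eight codes in the package's canonical
#' order. `five_posture_subset()` returns the default five-posture subset
#' used for the easier classification condition; the subset spans all
#' three joint axes. The subset is a documented reconstruction (the
#' original study's choice of five postures is not fully specified) and
#' every function that consumes posture lists accepts any subset.
#'
#' @return A character vector of posture codes.
#' @examples
#' all_postures()
#' five_posture_subset()
#' @export
all_postures <- function() {
  c("FFS", "FFP", "FES", "FEP", "EFS", "EFP", "EES", "EEP")
}

#' @rdname all_postures
#' @export
five_posture_subset <- function() {
  c("FFS", "FFP", "FES", "EFS", "EEP")
}

#' Validate and split a posture code
#'
#' @param code A 3-character posture code such as `"FFS"`.
#' @return A named character vector with elements `shoulder`, `elbow`,
#'   `wrist`.
#' @keywords internal
parse_posture <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 3L)
    stop("posture code must be a single 3-letter string, e.g. \"FFS\"", call. = FALSE)
  ch <- strsplit(toupper(code), "")[[1L]]
  if (!ch[1L] %in% c("F", "E") || !ch[2L] %in% c("F", "E") ||
      !ch[3L] %in% c("P", "S"))
    stop(sprintf("invalid posture code '%s': joints are {F,E}x{F,E}x{P,S}", code),
         call. = FALSE)
  c(shoulder = ch[1L], elbow = ch[2L], wrist = ch[3L])
}

is_posture <- function(code) {
  tryCatch({ parse_posture(code); TRUE }, error = function(e) FALSE)
}

#' Map a static posture to its cube corner
#'
#' Each posture occupies one corner of the normalized workspace cube
#' \eqn{[-1,1]^3} whose axes are shoulder, elbow and wrist excursion.
#' The default sign convention maps flexion (`F`) to +1 and extension
#' (`E`) to -1 on the shoulder and elbow axes, and supination (`S`) to
#' +1, pronation (`P`) to -1 on the wrist axis. Any of the eight
#' consistent conventions can be selected by flipping axis signs.
#'
#' @param code Posture code (see [all_postures()]).
#' @param axis_signs Numeric vector of length 3 with entries +1/-1,
#'   flipping the orientation of the shoulder, elbow and wrist axes.
#' @return Numeric 3-vector with entries in \{-1, +1\}, named
#'   `shoulder`, `elbow`, `wrist`.
#' @examples
#' posture_to_corner("FFS")  # c(1, 1, 1)
#' posture_to_corner("EEP")  # c(-1, -1, -1)
#' @export
posture_to_corner <- function(code, axis_signs = c(1, 1, 1)) {
  p <- parse_posture(code)
  if (length(axis_signs) != 3L || !all(abs(axis_signs) == 1))
    stop("'axis_signs' must be three values in {-1, +1}", call. = FALSE)
  base <- c(
    shoulder = if (p[["shoulder"]] == "F") 1 else -1,
    elbow    = if (p[["elbow"]] == "F") 1 else -1,
    wrist    = if (p[["wrist"]] == "S") 1 else -1
  )
  base * axis_signs
}
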