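#' The 19-node international 10-20 montage
#'
#' Electrode montage used throughout the package: 19 scalp electrodes of the
#' international 10-20 system define the network nodes, plus the A1/A2
#' earlobe reference electrodes. Odd indices are left-hemisphere sites, even
#' indices right-hemisphere, and the z-suffixed electrodes (Fz, Cz, Pz) lie
#' on the midline. Homologous left/right pairs (Fp1-Fp2, C3-C4, ...) drive
#' the lateral mirroring used to pool subjects with opposite affected sides.
#'
#' @return A list of class `Montage` with components:
#'   \describe{
#'     \item{labels}{character(19), network node labels in canonical order.}
#'     \item{refs}{character(2), the reference labels `A1`, `A2`.}
#'     \item{homolog_pairs}{named character vector mapping every lateral
#'       label (and each reference) to its contralateral homolog; an
#'       involution.}
#'     \item{midline}{character(3), `Fz`, `Cz`, `Pz`.}
#'   }
#' @examples
#' m <- standardMontage()
#' m$labels
#' m$homolog_pairs[["C3"]]
#' @export
standardMontage <- function() {
  labels <- c("Fp1", "F3", "C3", "P3", "O1",
              "Fp2", "F4", "C4", "P4", "O2",
              "F7", "T3", "T5", "F8", "T4", "T6",
              "Fz", "Cz", "Pz")
  left  <- c("Fp1", "F3", "F7", "C3", "T3", "T5", "P3", "O1", "A1")
  right <- c("Fp2", "F4", "F8", "C4", "T4", "T6", "P4", "O2", "A2")
  pairs <- stats::setNames(c(right, left), c(left, right))
  structure(list(labels = labels,
                 refs = c("A1", "A2"),
                 homolog_pairs = pairs,
                 midline = c("Fz", "Cz", "Pz")),
            class = "Montage")
}

#' @export
print.Montage <- function(x, ...) {
  cat("10-20 montage:", length(x$labels), "network nodes +",
      length(x$refs), "references\n")
  cat("  nodes:  ", paste(x$labels, collapse = " "), "\n")
  cat("  midline:", paste(x$midline, collapse = " "), "\n")
  invisible(x)
}

validateMontage <- function(m) {
  stopifnot(inherits(m, "Montage"))
  if (length(m$labels) != 19L || anyDuplicated(m$labels))
    stop("montage must have exactly 19 unique node labels")
  lateral <- setdiff(m$labels, m$midline)
  for (lab in lateral) {
    if (!lab %in% names(m$homolog_pairs))
      stop("lateral label without a homolog pair: ", lab)
  }
  ## pair mapping must be an involution
  for (lab in names(m$homolog_pairs)) {
    if (m$homolog_pairs[[m$homolog_pairs[[lab]]]] != lab)
      stop("homolog pair mapping is not an involution at ", lab)
  }
  invisible(TRUE)
}

## Scalp neighbor graph over the 19 nodes: geometric nearest neighbors on
## the 10-20 layout. Used as the fixed support of the zero-lag mixing
## operator that emulates instantaneous volume conduction.
montageNeighbors <- function(montage = standardMontage()) {
  edges <- list(
    c("Fp1", "Fp2"), c("Fp1", "F3"), c("Fp1", "F7"), c("Fp1", "Fz"),
    c("Fp2", "F4"), c("Fp2", "F8"), c("Fp2", "Fz"),
    c("F7", "F3"), c("F3", "Fz"), c("Fz", "F4"), c("F4", "F8"),
    c("F7", "T3"), c("F3", "C3"), c("Fz", "Cz"), c("F4", "C4"),
    c("F8", "T4"),
    c("T3", "C3"), c("C3", "Cz"), c("Cz", "C4"), c("C4", "T4"),
    c("T3", "T5"), c("C3", "P3"), c("Cz", "Pz"), c("C4", "P4"),
    c("T4", "T6"),
    c("T5", "P3"), c("P3", "Pz"), c("Pz", "P4"), c("P4", "T6"),
    c("T5", "O1"), c("P3", "O1"), c("Pz", "O1"), c("Pz", "O2"),
    c("P4", "O2"), c("T6", "O2"), c("O1", "O2"))
  n <- length(montage$labels)
  adj <- matrix(0, n, n, dimnames = list(montage$labels, montage$labels))
  for (e in edges) adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1
  adj
}
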