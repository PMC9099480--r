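#' Construct a daily transition matrix
#'
#' Wraps a 5x5 matrix of daily transition probabilities (rows = from-state,
#' columns = to-state, in [health_states()] order) together with the
#' structural mask of allowed transitions. Construction does not enforce
#' validity — use [validate_matrix()] to obtain a constraint-by-constraint
#' report; operations that require a valid matrix check it themselves.
#'
#' @param probs Numeric 5x5 matrix of daily transition probabilities.
#'   Dimnames, if present, must match [health_states()] in order.
#' @param mask Logical 5x5 matrix of structurally allowed transitions
#'   (default [default_mask()]).
#' @return Object of class `transition_matrix` with fields `probs` and `mask`.
#' @seealso [validate_matrix()], [run_cohort()], [read_matrix()]
#' @export
transition_matrix <- function(probs, mask = default_mask()) {
  s <- health_states()
  probs <- as.matrix(probs)
  if (!all(dim(probs) == c(5L, 5L))) {
    stop("`probs` must be a 5x5 matrix", call. = FALSE)
  }
  if (!is.null(dimnames(probs)) && !is.null(rownames(probs))) {
    if (!identical(rownames(probs), s) || !identical(colnames(probs), s)) {
      stop("dimnames of `probs` must be the five state labels in canonical order",
           call. = FALSE)
    }
  }
  dimnames(probs) <- list(s, s)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == c(5L, 5L)) || !is.logical(mask)) {
    stop("`mask` must be a 5x5 logical matrix", call. = FALSE)
  }
  dimnames(mask) <- list(s, s)
  structure(list(probs = probs, mask = mask), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("Daily transition matrix (5 health states)\n")
  print(round(x$probs, digits))
  v <- validate_matrix(x)
  cat(if (v$valid) "Valid.\n" else
    paste0("INVALID: ", paste(v$violations, collapse = "; "), "\n"))
  invisible(x)
}

#' Validate a transition matrix against the structural constraints
#'
#' Checks every invariant of the daily chain: entries are probabilities,
#' each row sums to one (within 1e-12), no probability mass sits on a
#' transition the structural mask forbids, and the death state is absorbing.
#' Violations are reported, not thrown, so a calibration or file-loading
#' pipeline can surface all problems at once.
#'
#' @param M A [transition_matrix()].
#' @return List with `valid` (logical) and `violations` (character vector;
#'   empty when valid). Violation strings are tagged `"row-sum"`, `"range"`,
#'   `"mask"` or `"absorbing"`.
#' @export
#' @examples
#' M <- transition_matrix(diag(5), mask = diag(5) > 0)
#' validate_matrix(M)$valid
validate_matrix <- function(M) {
  stopifnot(inherits(M, "transition_matrix"))
  p <- M$probs
  s <- health_states()
  viol <- character(0)
  if (any(!is.finite(p))) {
    viol <- c(viol, "range: non-finite entries")
  } else {
    if (any(p < 0 | p > 1)) {
      bad <- which(p < 0 | p > 1, arr.ind = TRUE)
      viol <- c(viol, sprintf("range: entry %s->%s = %g outside [0,1]",
                              s[bad[, 1]], s[bad[, 2]], p[bad]))
    }
    rs <- rowSums(p)
    off <- abs(rs - 1) > 1e-12
    if (any(off)) {
      viol <- c(viol, sprintf("row-sum: row %s sums to %.12g", s[off], rs[off]))
    }
    onmask <- p != 0 & !M$mask
    if (any(onmask)) {
      bad <- which(onmask, arr.ind = TRUE)
      viol <- c(viol, sprintf("mask: forbidden transition %s->%s has mass %g",
                              s[bad[, 1]], s[bad[, 2]], p[bad]))
    }
    if (M$mask["DEAD", "DEAD"] && !isTRUE(all.equal(unname(p["DEAD", ]),
                                                    c(0, 0, 0, 0, 1),
                                                    tolerance = 1e-12))) {
      viol <- c(viol, "absorbing: DEAD row is not the unit vector onto DEAD")
    }
  }
  list(valid = length(viol) == 0L, violations = viol)
}

stop_if_invalid <- function(M) {
  v <- validate_matrix(M)
  if (!v$valid) {
    stop("invalid transition matrix: ", paste(v$violations, collapse = "; "),
         call. = FALSE)
  }
  invisible(M)
}

#' Draw a random valid transition matrix
#'
#' Rows over the masked-allowed destinations are drawn from a flat Dirichlet
#' (normalized Exp(1) draws); the DEAD row is the absorbing unit vector.
#' Used for property-based testing and as calibration multi-start material.
#'
#' @param mask Structural mask (default [default_mask()]).
#' @return A valid [transition_matrix()].
#' @export
random_transition_matrix <- function(mask = default_mask()) {
  s <- health_states()
  p <- matrix(0, 5, 5, dimnames = list(s, s))
  for (i in seq_len(4)) {
    allowed <- which(mask[i, ])
    w <- stats::rexp(length(allowed))
    p[i, allowed] <- w / sum(w)
  }
  p["DEAD", "DEAD"] <- 1
  transition_matrix(p, mask)
}

#' Read / write transition matrices as delimited text
#'
#' Matrices are stored as tab-delimited 5x5 tables with a header row and a
#' leading column of state labels. `write_matrix()` writes the probabilities
#' and, alongside, `<file>.mask.tsv` with the structural mask, plus an
#' optional JSON sidecar `<file>.json` carrying provenance metadata.
#'
#' @param file Path of the probability table.
#' @param M A [transition_matrix()].
#' @param meta Optional named list written to the JSON sidecar.
#' @return `read_matrix()` returns a [transition_matrix()];
#'   `write_matrix()` returns `file` invisibly.
#' @export
read_matrix <- function(file) {
  p <- as.matrix(utils::read.delim(file, row.names = 1, check.names = FALSE))
  maskfile <- paste0(file, ".mask.tsv")
  mask <- if (file.exists(maskfile)) {
    as.matrix(utils::read.delim(maskfile, row.names = 1, check.names = FALSE)) > 0
  } else {
    default_mask()
  }
  transition_matrix(p, mask)
}

#' @rdname read_matrix
#' @export
write_matrix <- function(M, file, meta = NULL) {
  stopifnot(inherits(M, "transition_matrix"))
  utils::write.table(M$probs, file, sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(M$mask * 1L, paste0(file, ".mask.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(file, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(file)
}
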