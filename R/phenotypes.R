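#' Collapse phenotype replicates into a binary case status
#'
#' Summarises `m` independent binary phenotype replicates per individual into
#' one case/control status. With `l` the number of replicates in which an
#' individual is a case, the *specific* definition calls an individual a case
#' when `l/m >= 0.5` (hypertensive in at least half the replicates); the
#' *sensitive* definition when `l/m > 0` (hypertensive in at least one).
#' Specific cases are always a subset of sensitive cases.
#'
#' @param replicates Binary matrix, individuals x replicates, or a `cohort`
#'   (its replicate matrix is used).
#' @param mode `"specific"` or `"sensitive"`.
#' @param m Number of replicates to collapse; defaults to all provided. The
#'   first `m` columns of `replicate_ids` (or of the matrix) are used, in
#'   order.
#' @param replicate_ids Optional column names (or indices) selecting and
#'   ordering the replicate set before the first `m` are taken.
#' @return A `collapsed_phenotype`: list with `status` (named 0/1 vector),
#'   `m`, `mode`, and `source_replicate_ids`.
#' @examples
#' reps <- matrix(c(1, 1, 0, 0, 0,
#'                  1, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
#'                dimnames = list(c("a", "b"), paste0("SIMPHEN.", 1:5)))
#' collapse_phenotype(reps, "specific")$status   # both 2/5 and 1/5 < 0.5
#' collapse_phenotype(reps, "sensitive")$status  # both carry >= 1 case call
#' @export
collapse_phenotype <- function(replicates, mode = c("specific", "sensitive"),
                               m = NULL, replicate_ids = NULL) {
  mode <- match.arg(mode)
  if (inherits(replicates, "cohort")) replicates <- replicates$phenotype_replicates
  assert_binary_matrix(replicates, "replicate matrix")
  if (!is.null(replicate_ids)) {
    replicates <- replicates[, replicate_ids, drop = FALSE]
  }
  m <- m %||% ncol(replicates)
  if (!is_count(m) || m > ncol(replicates)) {
    stop("`m` must be a positive count no larger than the available replicates")
  }
  used <- replicates[, seq_len(m), drop = FALSE]
  l <- rowSums(used)
  status <- if (mode == "specific") as.integer(l / m >= 0.5) else as.integer(l > 0)
  names(status) <- rownames(replicates)
  structure(list(status = status, m = as.integer(m), mode = mode,
                 source_replicate_ids = colnames(used) %||% seq_len(m)),
            class = "collapsed_phenotype")
}

#' @export
print.collapsed_phenotype <- function(x, ...) {
  cat(sprintf("<collapsed_phenotype> mode=%s m=%d: %d cases / %d individuals\n",
              x$mode, x$m, sum(x$status), length(x$status)))
  invisible(x)
}

#' Write a collapsed phenotype as a one-column TSV
#'
#' The header line records the collapsing mode and depth as a comment so the
#' provenance travels with the file.
#'
#' @param phenotype A `collapsed_phenotype`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_phenotype <- function(phenotype, path) {
  stopifnot(inherits(phenotype, "collapsed_phenotype"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s m=%d", phenotype$mode, phenotype$m), con)
  write.table(data.frame(individual_id = names(phenotype$status),
                         status = phenotype$status),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
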