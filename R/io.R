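#' Read and write probability vectors as two-column CSV
#'
#' The on-disk format is a CSV with columns `state,prob`; lines starting
#' with `#` are metadata comments and are ignored on read.
#'
#' @param path File path.
#' @param tol Sum-to-one tolerance on read.
#' @return `read_prob_vector()` returns a [prob_vector()].
#' @export
read_prob_vector <- function(path, tol = 1e-9) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("character", "numeric"))
  if (!all(c("state", "prob") %in% names(df))) {
    stop("expected columns `state` and `prob` in ", path)
  }
  prob_vector(stats::setNames(df$prob, df$state), tol = tol)
}

#' @rdname read_prob_vector
#' @param pv A [prob_vector()].
#' @param meta Optional named character vector written as `# key=value`
#'   header lines.
#' @export
write_prob_vector <- function(pv, path, meta = NULL) {
  pv <- as_prob_vector(pv)
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, meta)
  utils::write.csv(data.frame(state = names(pv), prob = as.numeric(pv)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_meta <- function(con, meta) {
  if (is.null(meta)) return(invisible())
  meta <- c(version = as.character(utils::packageVersion("condind")), meta)
  writeLines(paste0("# ", names(meta), "=", meta), con)
}

#' Read and write joint count tables in long CSV format
#'
#' One column per variable plus a `count` column; every combination of
#' states present in the file becomes a cell, absent combinations are
#' zero. Lines starting with `#` are ignored on read.
#'
#' @param path File path.
#' @return `read_joint_table()` returns a [joint_count_table()].
#' @export
read_joint_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = "character")
  if (!"count" %in% names(df) || ncol(df) < 3L) {
    stop("expected >= 2 variable columns plus a `count` column in ", path)
  }
  vars <- setdiff(names(df), "count")
  dn <- lapply(df[vars], function(x) sort(unique(x)))
  counts <- array(0, dim = unname(vapply(dn, length, 0L)), dimnames = dn)
  idx <- as.matrix(do.call(cbind, lapply(vars, function(v) {
    match(df[[v]], dn[[v]])
  })))
  counts[idx] <- counts[idx] + as.numeric(df$count)
  joint_count_table(counts)
}

#' @rdname read_joint_table
#' @param table A [joint_count_table()].
#' @param meta Optional named character vector of `# key=value` headers.
#' @export
write_joint_table <- function(table, path, meta = NULL) {
  stopifnot(inherits(table, "joint_count_table"))
  long <- as.data.frame.table(table$counts, responseName = "count",
                              stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, meta)
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
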