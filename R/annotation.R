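#' Read a gold-label table
#'
#' The label schema mirrors the two-step manual annotation: an overall
#' impact flag, then — only for impacted messages — one flag per HRQoL
#' dimension.
#'
#' @param path CSV with columns `message_id`, `annotator`, `impact`,
#'   `physical`, `psychic`, `activity`, `relational`, `financial` (flags as
#'   0/1 or TRUE/FALSE).
#' @return A data frame with logical flag columns.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("message_id", "impact", qol_dimensions())
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("label table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$annotator)) df$annotator <- "unknown"
  to_flag <- function(v) {
    if (is.logical(v)) return(v)
    num <- suppressWarnings(as.numeric(v))
    ifelse(!is.na(num), num != 0, as.logical(v))
  }
  for (col in c("impact", qol_dimensions())) df[[col]] <- to_flag(df[[col]])
  df$message_id <- as.character(df$message_id)
  df
}

#' Write a gold-label table to CSV
#'
#' @param labels label data frame (see [read_labels()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  out <- labels
  for (col in c("impact", qol_dimensions())) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a label table against its corpus
#'
#' Checks the label invariants: a message without impact carries no
#' dimension flag; every captured expression span lies inside its message
#' text and its dimension flag is set; label `message_id`s resolve in the
#' corpus. Violations are reported, never fatal.
#'
#' @param labels label data frame (see [read_labels()]).
#' @param corpus the [qol_corpus] the labels refer to.
#' @param expressions optional captured-span table (`message_id`, `start`,
#'   `end`, `dimension`).
#' @return A list with `ok` (logical), `n_violations`, and `violations`
#'   (data frame with `message_id`, `rule`).
#' @export
validate_labels <- function(labels, corpus, expressions = NULL) {
  viol <- list()
  flag <- function(ids, rule) {
    if (length(ids)) {
      viol[[length(viol) + 1]] <<- data.frame(message_id = ids, rule = rule,
                                              stringsAsFactors = FALSE)
    }
  }
  dims <- qol_dimensions()
  any_dim <- Reduce(`|`, lapply(dims, function(d) labels[[d]]))
  flag(labels$message_id[!labels$impact & any_dim],
       "dimension flag set while impact is false")
  flag(labels$message_id[!labels$message_id %in% corpus$id],
       "label references unknown message_id")
  if (!is.null(expressions) && nrow(expressions) > 0) {
    text_by_id <- stats::setNames(corpus$text, corpus$id)
    lab_by_id <- labels[!duplicated(labels$message_id), , drop = FALSE]
    rownames(lab_by_id) <- lab_by_id$message_id
    for (i in seq_len(nrow(expressions))) {
      mid <- expressions$message_id[i]
      txt <- text_by_id[[mid]]
      if (is.null(txt)) {
        flag(mid, "expression references unknown message_id")
        next
      }
      s <- expressions$start[i]; e <- expressions$end[i]
      if (is.na(s) || is.na(e) || s < 0 || e <= s || e > nchar(txt)) {
        flag(mid, "expression span outside message text")
      }
      d <- expressions$dimension[i]
      if (mid %in% rownames(lab_by_id) && d %in% dims &&
          !isTRUE(lab_by_id[mid, d])) {
        flag(mid, paste0("expression tagged ", d,
                         " but dimension flag is false"))
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(message_id = character(0), rule = character(0),
               stringsAsFactors = FALSE)
  list(ok = nrow(violations) == 0, n_violations = nrow(violations),
       violations = violations)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement from the 2x2 table:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} where \eqn{p_o} is the observed
#' agreement and \eqn{p_e} the agreement expected from the marginals. In the
#' degenerate case \eqn{p_e = 1} (both raters constant and identical —
#' including two all-negative vectors, as happens for a dimension never
#' mentioned in the doubly annotated subset) the convention is
#' \eqn{\kappa = 0}.
#'
#' @param a,b logical vectors of equal length (one element per message).
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) {
    stop("rater vectors must have the same length", call. = FALSE)
  }
  if (length(a) < 1) stop("need at least one rated item", call. = FALSE)
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(0)
  (po - pe) / (1 - pe)
}

#' Inter-annotator agreement report
#'
#' Computes Cohen's kappa per label (overall impact plus the five
#' dimensions) for two label tables covering the same messages, as done on
#' a doubly-annotated subset to audit annotation homogeneity.
#'
#' @param labels_a,labels_b label data frames (see [read_labels()]) over
#'   the same set of `message_id`s.
#' @return An object of class `qol_agreement`: a data frame with columns
#'   `label`, `kappa`, `observed`, `expected`, plus attribute `n`.
#' @export
agreement_report <- function(labels_a, labels_b) {
  ids_a <- labels_a$message_id; ids_b <- labels_b$message_id
  sym <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
  if (length(sym)) {
    stop("label tables cover different messages: ",
         paste(utils::head(sym, 10), collapse = ", "), call. = FALSE)
  }
  b_ord <- labels_b[match(ids_a, ids_b), , drop = FALSE]
  targets <- c("impact", qol_dimensions())
  rows <- lapply(targets, function(t) {
    a <- as.logical(labels_a[[t]]); b <- as.logical(b_ord[[t]])
    po <- mean(a == b)
    pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
    data.frame(label = t, kappa = cohen_kappa(a, b), observed = po,
               expected = pe, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, n = length(ids_a),
            class = c("qol_agreement", "data.frame"))
}

#' @export
print.qol_agreement <- function(x, ...) {
  cat(sprintf("Inter-annotator agreement over %d messages\n", attr(x, "n")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-10s kappa = %6.3f (po = %.3f, pe = %.3f)\n",
                x$label[i], x$kappa[i], x$observed[i], x$expected[i]))
  }
  invisible(x)
}
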