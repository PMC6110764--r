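#' Construct a PSSM object
#'
#' A PSSM is the N x 20 matrix of per-residue log-odds substitution scores
#' that PSI-BLAST computes for a query protein: entry \eqn{\epsilon_{i,j}}
#' scores the substitution of residue i by amino-acid type j over the
#' protein family found by iterative profile search.  Only the integer
#' log-odds block of the PSI-BLAST ASCII output is represented; the
#' weighted-percentage block and trailing statistics are discarded.
#'
#' @param scores integer matrix with N >= 1 rows and exactly 20 columns.
#' @param protein_id character scalar naming the protein.
#' @param column_alphabet the amino-acid order of the 20 columns; must be a
#'   permutation of the 20 standard one-letter codes.  Defaults to the
#'   PSI-BLAST order \code{ARNDCQEGHILKMFPSTWYV}.
#' @return An object of class \code{"pssm"}: the score matrix with
#'   attributes \code{protein_id} and \code{column_alphabet}.
#' @examples
#' p <- pssm(matrix(0L, 3, 20), "toy")
#' n_residues(p)
#' @export
pssm <- function(scores, protein_id, column_alphabet = PSSM_ALPHABET) {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    stop("a PSSM must have exactly 20 columns, got ", ncol(scores))
  if (nrow(scores) < 1L)
    stop("a PSSM must have at least 1 residue row")
  if (any(!is.finite(scores)))
    stop("PSSM scores must be finite")
  if (any(scores != round(scores)))
    stop("PSSM scores must be integer log-odds")
  if (!is.character(protein_id) || length(protein_id) != 1L ||
      !nzchar(protein_id))
    stop("protein_id must be a non-empty string")
  if (length(column_alphabet) != 20L ||
      !setequal(column_alphabet, PSSM_ALPHABET))
    stop("column_alphabet must be a permutation of the 20 standard amino acids")
  storage.mode(scores) <- "integer"
  dimnames(scores) <- NULL
  structure(scores,
            protein_id = protein_id,
            column_alphabet = as.character(column_alphabet),
            class = "pssm")
}

#' @rdname pssm
#' @param x a \code{pssm} object.
#' @export
n_residues <- function(x) {
  stopifnot(inherits(x, "pssm"))
  nrow(x)
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM for '%s': %d residues x 20 amino-acid columns\n",
              attr(x, "protein_id"), nrow(x)))
  cat("column order:", paste(attr(x, "column_alphabet"), collapse = ""), "\n")
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the dialect written by \code{psiblast -out_ascii_pssm}: two header
#' lines (the second carrying the 40-letter column legend), then one line
#' per residue holding the position index, the query residue letter, 20
#' integer log-odds columns and 20 weighted-percentage columns, followed by
#' per-position statistics and trailing K/lambda lines.  Only the first 20
#' (log-odds) score columns are consumed.
#'
#' @param path path to the PSSM file.
#' @param protein_id protein identifier to attach; defaults to the file
#'   name without the \code{.pssm} extension.
#' @return A \code{\link{pssm}} object.
#' @seealso \code{\link{write_pssm}} for the inverse operation.
#' @export
read_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(protein_id))
    protein_id <- sub("\\.pssm$", "", basename(path))
  lines <- readLines(path, warn = FALSE)

  alphabet <- PSSM_ALPHABET
  rows <- list()
  row_lines <- integer(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 0L || !nzchar(tok[1L])) next
    if (length(tok) >= 40L && all(tok %in% PSSM_ALPHABET)) {
      # column legend line; first 20 letters give the score-column order
      alphabet <- tok[1:20]
      next
    }
    if (grepl("^[0-9]+$", tok[1L]) && length(tok) >= 2L &&
        grepl("^[A-Za-z]$", tok[2L])) {
      vals <- tok[-(1:2)]
      if (length(vals) < 20L)
        stop(sprintf("malformed PSSM row at line %d of %s: expected %s",
                     i, path, "at least 20 score columns"))
      sc <- suppressWarnings(as.numeric(vals[1:20]))
      if (any(is.na(sc)) || any(sc != round(sc)))
        stop(sprintf("non-integer score cell at line %d of %s", i, path))
      rows[[length(rows) + 1L]] <- as.integer(sc)
      row_lines <- c(row_lines, i)
    }
    # anything else (headers, K/lambda statistics) is ignored
  }
  if (length(rows) == 0L)
    stop("no residue rows found in ", path, ": empty PSSM")
  pssm(do.call(rbind, rows), protein_id, column_alphabet = alphabet)
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Emits the same dialect that \code{\link{read_pssm}} accepts, so that
#' write-then-read is the identity on the score matrix and column order.
#' The 20 weighted-percentage columns (not represented in a \code{pssm})
#' are written as zeros.
#'
#' @param x a \code{\link{pssm}} object.
#' @param path output file path.
#' @param residues optional character vector of residue letters (length =
#'   rows of \code{x}); defaults to "X" placeholders.
#' @return \code{path}, invisibly.
#' @export
write_pssm <- function(x, path, residues = NULL) {
  stopifnot(inherits(x, "pssm"))
  n <- nrow(x)
  if (is.null(residues)) residues <- rep("X", n)
  if (length(residues) != n)
    stop("residues must have one letter per PSSM row")
  alph <- attr(x, "column_alphabet")
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", c(alph, alph)), collapse = " "))
  )
  body <- vapply(seq_len(n), function(i) {
    paste0(sprintf("%5d %s ", i, residues[i]),
           paste(sprintf("%3d", x[i, ]), collapse = " "), " ",
           paste(sprintf("%3d", rep(0L, 20L)), collapse = " "),
           "  0.00 0.00")
  }, character(1))
  trailer <- c("", "                      K         Lambda",
               "Standard Ungapped    0.1337     0.3176")
  ok <- tryCatch({
    writeLines(c(header, body, trailer), path)
    TRUE
  }, error = function(e) {
    stop("cannot write PSSM to ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}

#' Read a pair list and its PSSMs into a pair dataset
#'
#' The pair list is plain whitespace- or tab-delimited text with one pair
#' per line: \code{id_A id_B label}, label 1 for an interacting pair and 0
#' for a non-interacting one (the balanced golden-standard layout used for
#' PPI benchmarks).  Each identifier must resolve to a file
#' \code{<id>.pssm} under \code{pssm_dir}.
#'
#' @param path path to the pair-list file.
#' @param pssm_dir directory holding one \code{<id>.pssm} file per protein.
#' @return A \code{"pair_dataset"} list with elements \code{pairs} (a
#'   data.frame with columns \code{id_a}, \code{id_b}, \code{label},
#'   preserving file order) and \code{pssms} (a named list of
#'   \code{\link{pssm}} objects).
#' @export
read_pair_list <- function(path, pssm_dir) {
  if (!file.exists(path)) stop("pair-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("pair list is empty: ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed pair line ", bad[1L], " in ", path,
         ": expected 'id_A id_B label'")
  id_a <- vapply(parts, `[`, character(1), 1L)
  id_b <- vapply(parts, `[`, character(1), 2L)
  lab_chr <- vapply(parts, `[`, character(1), 3L)
  if (!all(lab_chr %in% c("0", "1")))
    stop("labels must be 0 or 1; offending line ",
         which(!lab_chr %in% c("0", "1"))[1L], " in ", path)
  label <- as.integer(lab_chr)
  key <- paste(id_a, id_b, label)
  if (anyDuplicated(key))
    stop("duplicate pair at line ", which(duplicated(key))[1L], " in ", path)
  ids <- unique(c(id_a, id_b))
  files <- file.path(pssm_dir, paste0(ids, ".pssm"))
  missing <- ids[!file.exists(files)]
  if (length(missing))
    stop("missing PSSM files for: ", paste(missing, collapse = ", "))
  pssms <- lapply(ids, function(id)
    read_pssm(file.path(pssm_dir, paste0(id, ".pssm")), protein_id = id))
  names(pssms) <- ids
  pair_dataset(data.frame(id_a = id_a, id_b = id_b, label = label,
                          stringsAsFactors = FALSE),
               pssms)
}

#' @rdname read_pair_list
#' @param pairs data.frame with columns \code{id_a}, \code{id_b},
#'   \code{label}.
#' @param pssms named list of \code{\link{pssm}} objects covering every id
#'   in \code{pairs}.
#' @export
pair_dataset <- function(pairs, pssms) {
  stopifnot(is.data.frame(pairs),
            all(c("id_a", "id_b", "label") %in% names(pairs)))
  if (!all(pairs$label %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  key <- paste(pairs$id_a, pairs$id_b, pairs$label)
  if (anyDuplicated(key)) stop("duplicate (id_a, id_b, label) triples")
  ids <- unique(c(pairs$id_a, pairs$id_b))
  unresolved <- setdiff(ids, names(pssms))
  if (length(unresolved))
    stop("pairs reference proteins with no PSSM: ",
         paste(unresolved, collapse = ", "))
  stopifnot(all(vapply(pssms, inherits, logical(1), "pssm")))
  structure(list(pairs = pairs, pssms = pssms), class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf(
    "pair_dataset: %d pairs (%d interacting, %d non-interacting), %d proteins\n",
    nrow(x$pairs), sum(x$pairs$label == 1L), sum(x$pairs$label == 0L),
    length(x$pssms)))
  invisible(x)
}

#' Write a pair list to file
#'
#' @param dataset a \code{pair_dataset}.
#' @param path output path for the tab-delimited pair list.
#' @return \code{path}, invisibly.
#' @export
write_pair_list <- function(dataset, path) {
  stopifnot(inherits(dataset, "pair_dataset"))
  p <- dataset$pairs
  writeLines(paste(p$id_a, p$id_b, p$label, sep = "\t"), path)
  invisible(path)
}

#' Generate PSSMs with an external PSI-BLAST
#'
#' Thin wrapper around the \code{psiblast} executable: writes each protein
#' sequence to a temporary FASTA query, runs an iterative search against a
#' formatted protein database, and parses the resulting ASCII PSSM with
#' \code{\link{read_pssm}}.  No alignment logic is implemented here.  The
#' defaults (e-value 0.001, 3 iterations) are the standard settings for
#' building evolutionary profiles for PPI feature extraction.
#'
#' @param records named character vector (or named list) of protein
#'   sequences over the amino-acid alphabet; names are protein ids.
#' @param db path to a formatted protein BLAST database (e.g. SwissProt).
#' @param evalue inclusion e-value threshold, default 0.001.
#' @param iterations number of PSI-BLAST iterations, default 3.
#' @param psiblast path or name of the PSI-BLAST executable.
#' @return A named list of \code{\link{pssm}} objects, one per record.
#' @export
run_psiblast <- function(records, db, evalue = 0.001, iterations = 3,
                         psiblast = "psiblast") {
  records <- unlist(as.list(records))
  if (length(records) == 0L) return(stats::setNames(list(), character(0)))
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("records must be named by protein id")
  if (Sys.which(psiblast) == "" && !file.exists(psiblast))
    stop("PSI-BLAST executable '", psiblast, "' not found on PATH; ",
         "install NCBI BLAST+ or pass its location via `psiblast=`")
  out <- vector("list", length(records))
  names(out) <- names(records)
  for (id in names(records)) {
    qf <- tempfile(fileext = ".fasta")
    pf <- tempfile(fileext = ".pssm")
    on.exit(unlink(c(qf, pf)), add = TRUE)
    writeLines(c(paste0(">", id), records[[id]]), qf)
    status <- system2(psiblast,
                      c("-query", shQuote(qf), "-db", shQuote(db),
                        "-evalue", format(evalue, scientific = FALSE),
                        "-num_iterations", iterations,
                        "-out_ascii_pssm", shQuote(pf)),
                      stdout = TRUE, stderr = TRUE)
    err <- attr(status, "status")
    if (!is.null(err) && err != 0L)
      stop("psiblast failed for '", id, "' (exit ", err, "): ",
           paste(status, collapse = "\n"))
    out[[id]] <- read_pssm(pf, protein_id = id)
  }
  out
}
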