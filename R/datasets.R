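#' Read a pair table of interaction examples
#'
#' Reads plain-text pair files of the shape used by public DTI/DDI
#' benchmarks: one example per line with a drug SMILES, a partner (protein
#' amino-acid sequence for DTI, a second SMILES for DDI), a 0/1 interaction
#' label and, optionally, a real-valued affinity column. The delimiter
#' (tab, comma or whitespace) is auto-detected, as is an optional header
#' line (recognised by a non-numeric label field).
#'
#' @param path Path to the file.
#' @param task `"dti"` or `"ddi"`; recorded on the result.
#' @param affinity When `TRUE`, a 4th column of affinities (e.g. Kd) is
#'   expected and labels are derived with [label_davis()] using
#'   `threshold`; when `FALSE` the 3rd column must parse as 0/1.
#' @param threshold Affinity threshold passed to [label_davis()].
#' @return A `data.frame` with columns `drug_smiles`, `partner`, `label`
#'   and (when present) `affinity`, rows in file order.
#' @seealso [write_pair_table()], [split_examples()], [dataset_summary()]
#' @export
read_pair_table <- function(path, task = c("dti", "ddi"),
                            affinity = FALSE, threshold = 30) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("pair table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty pair table: ", path)
    return(empty_examples(task))
  }
  sep <- detect_sep(lines[[1L]])
  fields <- lapply(lines, split_fields, sep = sep)
  lab_col <- 3L
  first <- fields[[1L]]
  header <- length(first) >= lab_col &&
    is.na(suppressWarnings(as.numeric(first[[lab_col]])))
  start <- if (header) 2L else 1L
  if (start > length(lines)) return(empty_examples(task))
  n <- length(lines) - start + 1L
  drug <- character(n); partner <- character(n)
  label <- integer(n); aff <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ln <- start + i - 1L
    f <- fields[[ln]]
    if (length(f) < 3L)
      stop_parse("line ", ln, ": expected >= 3 columns, got ", length(f))
    drug[i] <- f[[1L]]; partner[i] <- f[[2L]]
    if (affinity) {
      acol <- if (length(f) >= 4L) f[[4L]] else f[[3L]]
      a <- suppressWarnings(as.numeric(acol))
      if (is.na(a))
        stop_parse("line ", ln, ": affinity '", acol, "' is not numeric")
      aff[i] <- a
      label[i] <- label_davis(a, threshold)
    } else {
      v <- suppressWarnings(as.numeric(f[[3L]]))
      if (is.na(v) || !v %in% c(0, 1))
        stop_parse("line ", ln, ": label '", f[[3L]],
                   "' is not 0/1 (use affinity = TRUE for Kd columns)")
      label[i] <- as.integer(v)
      if (length(f) >= 4L)
        aff[i] <- suppressWarnings(as.numeric(f[[4L]]))
    }
    if (!nzchar(drug[i]) || !nzchar(partner[i]))
      stop_parse("line ", ln, ": empty drug or partner field")
  }
  out <- data.frame(drug_smiles = drug, partner = partner, label = label,
                    stringsAsFactors = FALSE)
  if (any(!is.na(aff))) out$affinity <- aff
  attr(out, "task") <- task
  out
}

empty_examples <- function(task) {
  out <- data.frame(drug_smiles = character(), partner = character(),
                    label = integer(), stringsAsFactors = FALSE)
  attr(out, "task") <- task
  out
}

detect_sep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else "[ ]+"
}

split_fields <- function(line, sep) {
  trimws(strsplit(trimws(line), sep)[[1L]])
}

#' Write a pair table
#'
#' Tab-separated, no header; the inverse of [read_pair_table()] so splits
#' round-trip byte-identically.
#'
#' @param examples Example `data.frame` (as returned by [read_pair_table()]
#'   or [gen_dataset()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(examples, path) {
  cols <- c("drug_smiles", "partner", "label")
  if (!is.null(examples$affinity)) cols <- c(cols, "affinity")
  lines <- do.call(paste, c(unname(as.list(examples[cols])), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Binarise a Davis-style affinity
#'
#' Pairs with dissociation constant strictly below the threshold are
#' labelled positive: `1` iff `kd < threshold`, else `0` (the boundary
#' value itself is negative).
#'
#' @param kd Non-negative affinity value(s).
#' @param threshold Positivity threshold (default 30, in the units of the
#'   supplied Kd column).
#' @return Integer 0/1 vector of the same length as `kd`.
#' @export
label_davis <- function(kd, threshold = 30) {
  if (any(is.na(kd)))
    stop("missing Kd value; supply pre-labelled files instead")
  as.integer(kd < threshold)
}

#' Split examples into train/valid/test
#'
#' Seeded uniform random split. The valid and test sets get
#' `floor(ratio * N)` examples each, the train set the remainder; the
#' three parts are disjoint and their union is exactly the input.
#' Optionally stratifies by label (same floor rule applied per class).
#'
#' @param examples Example `data.frame`.
#' @param ratios Length-3 non-negative numeric `(train, valid, test)`
#'   summing to 1.
#' @param seed Integer seed; identical seeds give identical membership.
#' @param stratify Logical; when `TRUE` the split is performed within each
#'   label class.
#' @return Named list `train`, `valid`, `test` of example data frames.
#' @export
split_examples <- function(examples, ratios = c(0.8, 0.1, 0.1), seed = 0L,
                           stratify = FALSE) {
  if (length(ratios) != 3L || any(ratios < 0))
    stop_config("ratios must be 3 non-negative numbers")
  if (abs(sum(ratios) - 1) > 1e-9)
    stop_config("ratios must sum to 1 (got ", sum(ratios), ")")
  n <- nrow(examples)
  assign_idx <- function(idx) {
    m <- length(idx)
    n_valid <- floor(ratios[2L] * m)
    n_test <- floor(ratios[3L] * m)
    perm <- idx[sample.int(m)]
    list(valid = perm[seq_len(n_valid)],
         test = perm[n_valid + seq_len(n_test)],
         train = perm[setdiff(seq_len(m), seq_len(n_valid + n_test))])
  }
  parts <- with_seed(seed, {
    if (stratify && n > 0L) {
      by_class <- lapply(split(seq_len(n), examples$label), assign_idx)
      list(train = sort(unlist(lapply(by_class, `[[`, "train"))),
           valid = sort(unlist(lapply(by_class, `[[`, "valid"))),
           test = sort(unlist(lapply(by_class, `[[`, "test"))))
    } else assign_idx(seq_len(n))
  })
  lapply(parts[c("train", "valid", "test")], function(ix) {
    out <- examples[ix, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "task") <- attr(examples, "task")
    out
  })
}

#' Summary counts of an example set
#'
#' @param examples Example `data.frame`.
#' @return Named list: `drugs` (unique drug SMILES), `partners` (unique
#'   partners), `samples` (rows), `positives` (label-1 rows).
#' @export
dataset_summary <- function(examples) {
  list(drugs = length(unique(examples$drug_smiles)),
       partners = length(unique(examples$partner)),
       samples = nrow(examples),
       positives = sum(examples$label == 1L))
}
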