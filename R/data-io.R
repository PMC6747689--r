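#' Read a fingerprint/descriptor table in the PaDEL CSV dialect
#'
#' PaDEL-Descriptor writes one CSV per fingerprint type: a header row, the
#' first column holding the compound name, and the remaining columns the
#' fingerprint bits (or counts). This reader validates the table against the
#' declared `kind`: any non-numeric cell, duplicated compound id, or value
#' outside the kind's domain is an error — missing values are never imputed.
#'
#' @param path path to the CSV file.
#' @param block_id identifier to assign to the block.
#' @param kind `"binary"`, `"count"` or `"continuous"`.
#' @return a [feature_block()].
#' @export
read_feature_table <- function(path, block_id, kind) {
  if (!file.exists(path)) abort("feature table not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = NA)
  if (ncol(df) < 2)
    abort("feature table %s: need an id column plus at least one feature", path)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  numeric_cols <- vapply(vals, function(col) {
    is.numeric(col) || !anyNA(suppressWarnings(as.numeric(col)))
  }, logical(1))
  if (!all(numeric_cols))
    abort("feature table %s: non-numeric cells in column(s) %s", path,
          paste(names(vals)[!numeric_cols], collapse = ", "))
  m <- vapply(vals, function(col) as.numeric(col), numeric(nrow(df)))
  if (nrow(df) == 1) m <- matrix(m, nrow = 1)
  feature_block(block_id, kind, m, compound_ids = ids,
                feature_names = names(vals))
}

#' Write a feature block as a PaDEL-dialect CSV
#'
#' Inverse of [read_feature_table()]: first column `Name`, one column per
#' feature. `read_feature_table(write_feature_table(b, f), ...)` returns a
#' block identical to `b`.
#'
#' @param block a [feature_block()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(block, path) {
  df <- data.frame(Name = block$compound_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[block$feature_names] <- as.data.frame(block$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read compound labels
#'
#' Reads a two-column CSV (`id,label`). Labels may be coded `0`/`1` or with
#' the DILIrank vocabulary `no-DILI`/`most-DILI` (1 = most-DILI, i.e.
#' hepatotoxicant).
#'
#' @param path path to the labels CSV.
#' @return named integer vector of 0/1, names = compound ids.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort("label file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort("label file %s: expected two columns (id, label)", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    abort("label file %s: duplicate compound id '%s'", path,
          ids[anyDuplicated(ids)])
  tok <- trimws(as.character(df[[2]]))
  lab <- ifelse(tok %in% c("1", "most-DILI"), 1L,
                ifelse(tok %in% c("0", "no-DILI"), 0L, NA_integer_))
  if (anyNA(lab))
    abort("label file %s: unknown label token '%s'", path, tok[which(is.na(lab))[1]])
  stats::setNames(lab, ids)
}

#' Write compound labels
#'
#' @param labels named 0/1 vector as returned by [read_labels()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(
    data.frame(Name = names(labels), label = as.integer(labels)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract compound identifiers from an SDF file
#'
#' Reads a multi-record V2000/V3000 SDF and returns one identifier per
#' record, in file order. The id is taken from the named data field when
#' present (by default the PubChem CID field), otherwise from the molecule
#' title line. Used only to align precomputed feature tables with an SDF:
#' no chemistry is perceived.
#'
#' @param path path to the SDF file.
#' @param id_field SDF data field holding the id (default
#'   `"PUBCHEM_COMPOUND_CID"`).
#' @return character vector of ids, one per record (empty for an empty file).
#' @export
extract_sdf_ids <- function(path, id_field = "PUBCHEM_COMPOUND_CID") {
  if (!file.exists(path)) abort("SDF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) return(character(0))
  # chemistry validity is irrelevant here: only record ids are read
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  vapply(seq_along(ChemmineR::cid(sdf)), function(i) {
    rec <- sdf[[i]]
    db <- ChemmineR::datablock(rec)
    if (id_field %in% names(db)) return(as.character(db[[id_field]]))
    title <- ChemmineR::header(rec)[["Molecule_Name"]]
    as.character(title)
  }, character(1))
}

#' Assemble an aligned, labelled dataset from feature blocks
#'
#' Restricts all blocks and the label vector to the compounds present in
#' every block AND in the labels, preserving the first block's row order,
#' and reports how many compounds were dropped. Alignment by intersection
#' (rather than erroring on mismatch) reflects real pipelines where a
#' compound can lack an identifier in one source.
#'
#' @param blocks list of [feature_block()]s (names are taken from each
#'   block's `block_id`).
#' @param labels named 0/1 vector ([read_labels()]).
#' @return an object of class `dili_dataset` with fields `compound_ids`,
#'   `labels`, `blocks`.
#' @export
assemble_dataset <- function(blocks, labels) {
  if (length(blocks) < 1) abort("need at least one feature block")
  for (b in blocks) validate_feature_block(b)
  ids <- Reduce(intersect, lapply(blocks, `[[`, "compound_ids"))
  ids <- ids[ids %in% names(labels)]
  # keep first block's order
  ids <- blocks[[1]]$compound_ids[blocks[[1]]$compound_ids %in% ids]
  if (length(ids) == 0) abort("empty intersection of compound ids")
  n_all <- length(unique(unlist(c(lapply(blocks, `[[`, "compound_ids"),
                                  list(names(labels))))))
  dropped <- n_all - length(ids)
  if (dropped > 0)
    message(sprintf("assemble_dataset: dropped %d compound(s) absent from some block or unlabelled; %d kept",
                    dropped, length(ids)))
  blocks_out <- lapply(blocks, function(b) {
    idx <- match(ids, b$compound_ids)
    feature_block(b$block_id, b$kind, b$values[idx, , drop = FALSE],
                  compound_ids = ids, feature_names = b$feature_names)
  })
  names(blocks_out) <- vapply(blocks_out, `[[`, "", "block_id")
  y <- as.integer(labels[ids])
  ds <- structure(list(compound_ids = ids,
                       labels = stats::setNames(y, ids),
                       blocks = blocks_out),
                  class = "dili_dataset")
  validate_dataset(ds)
}

#' Validate a labelled dataset
#'
#' @param ds a `dili_dataset`.
#' @return `ds`; errors if any block is misaligned or only one class is
#'   present.
#' @export
validate_dataset <- function(ds) {
  for (b in ds$blocks) {
    validate_feature_block(b)
    if (!identical(b$compound_ids, ds$compound_ids))
      abort("block '%s' is not aligned with the dataset compound ids",
            b$block_id)
  }
  if (!all(ds$labels %in% c(0L, 1L))) abort("labels must be 0/1")
  if (length(unique(ds$labels)) < 2) abort("single-class dataset")
  ds
}

#' @export
print.dili_dataset <- function(x, ...) {
  cat(sprintf("<dili_dataset> %d compounds (%d positive / %d negative), %d blocks\n",
              length(x$compound_ids), sum(x$labels == 1), sum(x$labels == 0),
              length(x$blocks)))
  for (b in x$blocks)
    cat(sprintf("  %-16s %-10s %5d features\n", b$block_id, b$kind,
                ncol(b$values)))
  invisible(x)
}

#' Subset a dataset by row index
#'
#' @param ds a `dili_dataset`.
#' @param idx integer row indices (compounds) to keep.
#' @param check when `TRUE` (default) the result must still contain both
#'   classes.
#' @return the subsetted `dili_dataset`.
#' @export
dataset_subset <- function(ds, idx, check = TRUE) {
  ids <- ds$compound_ids[idx]
  blocks <- lapply(ds$blocks, function(b)
    feature_block(b$block_id, b$kind, b$values[idx, , drop = FALSE],
                  compound_ids = ids, feature_names = b$feature_names))
  names(blocks) <- names(ds$blocks)
  out <- structure(list(compound_ids = ids, labels = ds$labels[idx],
                        blocks = blocks), class = "dili_dataset")
  if (check) validate_dataset(out) else out
}

#' Column-concatenate feature blocks into one design matrix
#'
#' Concatenation is how ranked fingerprints are "added" during greedy
#' selection and how the ensemble's fingerprint side sees its top blocks.
#' Feature names are prefixed with the block id to stay unique.
#'
#' @param ds a `dili_dataset`.
#' @param block_ids character vector of block ids to concatenate, in order.
#' @return numeric matrix with compounds in rows.
#' @export
concat_blocks <- function(ds, block_ids) {
  missing <- setdiff(block_ids, names(ds$blocks))
  if (length(missing))
    abort("dataset has no block(s): %s", paste(missing, collapse = ", "))
  mats <- lapply(block_ids, function(id) {
    b <- ds$blocks[[id]]
    m <- b$values
    colnames(m) <- paste(id, b$feature_names, sep = ".")
    m
  })
  out <- do.call(cbind, mats)
  rownames(out) <- ds$compound_ids
  out
}
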