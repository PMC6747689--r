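#' Catalogue of the twelve fingerprint families
#'
#' The twelve PaDEL fingerprint families consumed by the toolkit, with their
#' canonical block identifiers, pattern type, full bit width, and value kind
#' (`binary` for presence/absence bits, `count` for substructure-count
#' variants). Rows are in the canonical display order used by the accuracy
#' grid.
#'
#' @return a data.frame with columns `block_id`, `pattern_type`, `width`,
#'   `kind`.
#' @export
#' @examples
#' fingerprint_catalog()
fingerprint_catalog <- function() {
  data.frame(
    block_id = c("AP2DFP", "EstateFP", "ExtendedFP", "FP", "GraphOnlyFP",
                 "KRFP", "MaccsFP", "nAP2DFP", "nKRFP", "nSubstructreFP",
                 "PubchemFP", "SubstructreFP"),
    pattern_type = c("2D atom pairs", "E-state", "CDK extended hash",
                     "CDK hash", "CDK graph-only hash", "Klekota-Roth",
                     "MACCS", "2D atom pairs count", "Klekota-Roth count",
                     "substructure count", "PubChem", "substructure"),
    width = c(780L, 79L, 1024L, 1024L, 1024L, 4860L, 166L, 780L, 4860L,
              307L, 881L, 307L),
    kind = c("binary", "binary", "binary", "binary", "binary", "binary",
             "binary", "count", "count", "count", "binary", "binary"),
    stringsAsFactors = FALSE
  )
}

#' The seven physicochemical descriptors
#'
#' Names of the descriptor block columns: Ghose-Crippen logP (AlogP),
#' molecular weight (MW), aromatic ring count (nAR), hydrogen-bond acceptor
#' and donor counts (nHBA, nHBD), rotatable-bond count (nRTB) and ring
#' count (nR).
#'
#' @return character vector of length 7.
#' @export
descriptor_names <- function() {
  c("AlogP", "MW", "nAR", "nHBA", "nHBD", "nRTB", "nR")
}

#' Construct a feature block
#'
#' A feature block is one fingerprint or descriptor matrix together with its
#' aligned compound identifiers. `kind` declares the value domain and is
#' enforced: `binary` blocks must contain only 0/1, `count` blocks only
#' non-negative integers.
#'
#' @param block_id block identifier, e.g. one of
#'   `fingerprint_catalog()$block_id` or `"DESCRIPTORS"`.
#' @param kind one of `"binary"`, `"count"`, `"continuous"`.
#' @param values numeric matrix, compounds in rows.
#' @param compound_ids character vector of unique compound identifiers
#'   (default: `rownames(values)`).
#' @param feature_names character vector of unique feature names (default:
#'   `colnames(values)`).
#' @return an object of class `dili_feature_block`.
#' @export
feature_block <- function(block_id, kind, values,
                          compound_ids = rownames(values),
                          feature_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  block <- structure(
    list(block_id = as.character(block_id),
         kind = match.arg(kind, c("binary", "count", "continuous")),
         compound_ids = as.character(compound_ids),
         feature_names = as.character(feature_names),
         values = unname(values)),
    class = "dili_feature_block"
  )
  validate_feature_block(block)
}

#' Validate a feature block
#'
#' Checks the structural invariants: matrix shape matches the id/name
#' vectors, compound ids are unique, values are finite and respect the
#' declared kind.
#'
#' @param block a `dili_feature_block`.
#' @return the block, invisibly usable; errors on any violation.
#' @export
validate_feature_block <- function(block) {
  v <- block$values
  if (length(block$compound_ids) != nrow(v))
    abort("block '%s': %d compound ids for %d rows", block$block_id,
          length(block$compound_ids), nrow(v))
  if (length(block$feature_names) != ncol(v))
    abort("block '%s': %d feature names for %d columns", block$block_id,
          length(block$feature_names), ncol(v))
  if (anyDuplicated(block$compound_ids))
    abort("block '%s': duplicate compound ids", block$block_id)
  if (anyDuplicated(block$feature_names))
    abort("block '%s': duplicate feature names", block$block_id)
  if (anyNA(v) || any(!is.finite(v)))
    abort("block '%s': missing or non-finite values are not allowed",
          block$block_id)
  if (block$kind == "binary" && !all(v %in% c(0, 1)))
    abort("binary block '%s' contains non-binary value", block$block_id)
  if (block$kind == "count" && (any(v < 0) || any(v != floor(v))))
    abort("count block '%s' contains negative or non-integer value",
          block$block_id)
  block
}

#' @export
print.dili_feature_block <- function(x, ...) {
  cat(sprintf("<dili_feature_block> %s (%s): %d compounds x %d features\n",
              x$block_id, x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.dili_feature_block <- function(x) dim(x$values)

# matrix view with dimnames attached
block_matrix <- function(block) {
  m <- block$values
  dimnames(m) <- list(block$compound_ids, block$feature_names)
  m
}
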