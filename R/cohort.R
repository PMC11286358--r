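#' Nonsynonymous mutation-type whitelist
#'
#' The mutation channel of the genotype tensor is set only for nonsynonymous
#' coding events: missense, nonsense and nonstop mutations, frameshift
#' insertions/deletions, splice-site/region variants, and in-frame
#' insertions/deletions. Silent/synonymous and non-coding classes are ignored.
#' Types are compared after [normalize_mutation_type()].
#'
#' @return Character vector of normalized mutation-type strings.
#' @export
mutation_whitelist <- function() {
  c(
    "missense", "nonsense", "nonstop",
    "frameshift_insertion", "frameshift_deletion",
    "splice_site", "splice_region",
    "in_frame_insertion", "in_frame_deletion"
  )
}

#' Normalize a mutation-type string
#'
#' Lowercases, trims, and converts spaces/hyphens/slashes to underscores so
#' that e.g. `"Missense"`, `"missense "` and `"MISSENSE"` compare equal.
#'
#' @param x Character vector of mutation-type strings.
#' @return Normalized character vector.
#' @export
normalize_mutation_type <- function(x) {
  gsub("[ /-]+", "_", tolower(trimws(as.character(x))))
}

# MAF Variant_Classification -> whitelist vocabulary. Classes absent from the
# map (Silent, UTRs, introns, IGR, RNA, ...) are non-coding or synonymous and
# are dropped by the MAF reader.
maf_classification_map <- function() {
  c(
    Missense_Mutation = "missense",
    Nonsense_Mutation = "nonsense",
    Nonstop_Mutation = "nonstop",
    Frame_Shift_Ins = "frameshift_insertion",
    Frame_Shift_Del = "frameshift_deletion",
    Splice_Site = "splice_site",
    Splice_Region = "splice_region",
    In_Frame_Ins = "in_frame_insertion",
    In_Frame_Del = "in_frame_deletion"
  )
}

#' Read mutation calls from a MAF file
#'
#' Reads the `Tumor_Sample_Barcode`, `Hugo_Symbol` and `Variant_Classification`
#' columns of a (tab-delimited, possibly `#`-commented) MAF and maps variant
#' classifications onto the nonsynonymous whitelist vocabulary. Rows whose
#' classification has no mapping (synonymous or non-coding) are dropped with a
#' message.
#'
#' @param path Path to a MAF file.
#' @return A tibble of alteration calls with columns `sample`, `gene`,
#'   `class` (all `"mutation"`), `mutation_type`.
#' @export
read_maf_calls <- function(path) {
  maf <- utils::read.table(
    path,
    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    comment.char = "#", quote = ""
  )
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  if (!all(need %in% names(maf))) {
    stop(
      "MAF is missing column(s): ",
      paste(setdiff(need, names(maf)), collapse = ", "), call. = FALSE
    )
  }
  map <- maf_classification_map()
  mapped <- map[maf$Variant_Classification]
  dropped <- sum(is.na(mapped))
  if (dropped > 0) {
    message(dropped, " MAF row(s) with non-whitelisted classifications dropped")
  }
  keep <- !is.na(mapped)
  tibble::tibble(
    sample = maf$Tumor_Sample_Barcode[keep],
    gene = trimws(maf$Hugo_Symbol[keep]),
    class = "mutation",
    mutation_type = unname(mapped[keep])
  )
}

#' Read long-form alteration calls
#'
#' @param path Tab-delimited file with header columns `sample`, `gene`,
#'   `class`, and (for mutations) `mutation_type`.
#' @return A tibble of alteration calls.
#' @export
read_alteration_calls <- function(path) {
  calls <- utils::read.table(
    path,
    sep = "\t", header = TRUE, stringsAsFactors = FALSE, quote = ""
  )
  need <- c("sample", "gene", "class")
  if (!all(need %in% names(calls))) {
    stop(
      "alteration file is missing column(s): ",
      paste(setdiff(need, names(calls)), collapse = ", "), call. = FALSE
    )
  }
  if (!"mutation_type" %in% names(calls)) calls$mutation_type <- NA_character_
  tibble::as_tibble(calls)
}

new_genotype_tensor <- function(samples, genes, mutation, amplification,
                                deletion) {
  dimnames(mutation) <- dimnames(amplification) <- dimnames(deletion) <-
    list(samples, genes)
  structure(
    list(
      samples = samples, genes = genes,
      mutation = mutation, amplification = amplification, deletion = deletion
    ),
    class = "genotype_tensor"
  )
}

#' Encode alteration calls as a binary genotype tensor
#'
#' Produces the model input: a samples x genes x 3 binary tensor with channels
#' mutation, copy-number amplification (CNA) and copy-number deletion (CND).
#' The mutation channel is set only for calls whose `mutation_type` is on the
#' nonsynonymous whitelist; amplification/deletion calls set their channels
#' directly. Genes without calls stay all-zero. Calls for genes outside the
#' panel are dropped with a message reporting the count.
#'
#' @param calls Data frame with columns `sample`, `gene`, `class`
#'   (`"mutation"`, `"amplification"` or `"deletion"`), and `mutation_type`
#'   for mutation rows.
#' @param panel Character vector of gene symbols; fixes gene order.
#' @param samples Optional character vector fixing sample order; defaults to
#'   order of first appearance in `calls`.
#' @param whitelist Mutation-type whitelist (normalized strings).
#' @return A `genotype_tensor`.
#' @export
encode_genotypes <- function(calls, panel, samples = NULL,
                             whitelist = mutation_whitelist()) {
  stopifnot(is.data.frame(calls))
  panel <- unique(trimws(as.character(panel)))
  if (length(panel) == 0) stop("empty gene panel", call. = FALSE)
  calls <- tibble::as_tibble(calls)
  if (!"mutation_type" %in% names(calls)) calls$mutation_type <- NA_character_
  calls$gene <- trimws(as.character(calls$gene))
  calls$sample <- as.character(calls$sample)

  bad_class <- setdiff(
    unique(calls$class), c("mutation", "amplification", "deletion")
  )
  if (length(bad_class) > 0) {
    stop(
      "malformed alteration class(es): ", paste(bad_class, collapse = ", "),
      call. = FALSE
    )
  }

  off_panel <- !(calls$gene %in% panel)
  if (any(off_panel)) {
    message(sum(off_panel), " call(s) for genes outside the panel dropped")
    calls <- calls[!off_panel, , drop = FALSE]
  }

  if (is.null(samples)) samples <- unique(calls$sample)
  samples <- as.character(samples)
  calls <- calls[calls$sample %in% samples, , drop = FALSE]

  zero <- matrix(0, nrow = length(samples), ncol = length(panel))
  G <- new_genotype_tensor(samples, panel, zero, zero, zero)

  si <- match(calls$sample, samples)
  gi <- match(calls$gene, panel)
  is_mut <- calls$class == "mutation" &
    normalize_mutation_type(calls$mutation_type) %in% whitelist
  is_amp <- calls$class == "amplification"
  is_del <- calls$class == "deletion"
  G$mutation[cbind(si[is_mut], gi[is_mut])] <- 1
  G$amplification[cbind(si[is_amp], gi[is_amp])] <- 1
  G$deletion[cbind(si[is_del], gi[is_del])] <- 1
  G
}

#' Zero out genes that were not assessed
#'
#' External cohorts (clinical panels, xenografts) rarely assess the full gene
#' set used in training; genes absent from the assessed set are represented as
#' unaltered — all three channels zeroed. Shape and gene order are unchanged.
#'
#' @param G A `genotype_tensor`.
#' @param assessed Character vector of assessed gene symbols.
#' @return The masked `genotype_tensor`.
#' @export
mask_unassessed <- function(G, assessed) {
  stopifnot(inherits(G, "genotype_tensor"))
  off <- !(G$genes %in% assessed)
  if (any(off)) {
    G$mutation[, off] <- 0
    G$amplification[, off] <- 0
    G$deletion[, off] <- 0
  }
  G
}

subset_genotypes <- function(G, idx) {
  new_genotype_tensor(
    G$samples[idx], G$genes,
    G$mutation[idx, , drop = FALSE],
    G$amplification[idx, , drop = FALSE],
    G$deletion[idx, , drop = FALSE]
  )
}

#' @export
print.genotype_tensor <- function(x, ...) {
  cat(
    "<genotype_tensor> ", length(x$samples), " samples x ", length(x$genes),
    " genes x 3 channels; ",
    sum(x$mutation), " mutations, ", sum(x$amplification), " CNAs, ",
    sum(x$deletion), " CNDs\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a genotype tensor into long form
#'
#' @param x A `genotype_tensor`.
#' @param ... Unused.
#' @return A tibble with one row per nonzero entry: `sample`, `gene`,
#'   `channel`.
#' @method tidy genotype_tensor
#' @export
tidy.genotype_tensor <- function(x, ...) {
  chan <- function(mat, name) {
    idx <- which(mat == 1, arr.ind = TRUE)
    tibble::tibble(
      sample = x$samples[idx[, 1]],
      gene = x$genes[idx[, 2]],
      channel = name
    )
  }
  dplyr::bind_rows(
    chan(x$mutation, "mutation"),
    chan(x$amplification, "amplification"),
    chan(x$deletion, "deletion")
  )
}

#' Load a drug-response table
#'
#' @param path Tab-delimited file with header columns `sample`, `drug`, `auc`
#'   and optionally `replicate`. Replicate measurements are kept as separate
#'   rows (each replicate is a separate training instance).
#' @return A validated tibble.
#' @export
load_responses <- function(path) {
  rt <- utils::read.table(
    path,
    sep = "\t", header = TRUE, stringsAsFactors = FALSE, quote = ""
  )
  validate_responses(tibble::as_tibble(rt))
}

#' Validate a drug-response table
#'
#' @param rt Data frame with columns `sample`, `drug`, `auc` and optionally
#'   `replicate`. AUC must be non-negative; values above 1 are legitimate
#'   (drug-conferred growth advantage).
#' @return The table as a tibble, with a `replicate` column added if absent.
#' @export
validate_responses <- function(rt) {
  stopifnot(is.data.frame(rt))
  need <- c("sample", "drug", "auc")
  if (!all(need %in% names(rt))) {
    stop(
      "response table is missing column(s): ",
      paste(setdiff(need, names(rt)), collapse = ", "), call. = FALSE
    )
  }
  if (nrow(rt) == 0) stop("empty response table", call. = FALSE)
  if (!is.numeric(rt$auc) || any(!is.finite(rt$auc))) {
    stop("auc must be finite numeric", call. = FALSE)
  }
  if (any(rt$auc < 0)) stop("negative AUC values are invalid", call. = FALSE)
  rt <- tibble::as_tibble(rt)
  if (!"replicate" %in% names(rt)) rt$replicate <- NA_character_
  rt
}

#' Select drugs with variable responses measured in enough samples
#'
#' Keeps drugs whose AUC standard deviation (sample s.d., n-1 denominator)
#' meets `min_sd` and that were measured in at least `min_n` distinct samples.
#'
#' @param rt A response table (see [validate_responses()]).
#' @param min_sd Minimum per-drug AUC standard deviation (default 0.3).
#' @param min_n Minimum number of distinct samples per drug (default 200).
#' @return Character vector of retained drug ids.
#' @export
select_variable_drugs <- function(rt, min_sd = 0.3, min_n = 200) {
  rt <- validate_responses(rt)
  stats_tbl <- rt |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      sd_auc = stats::sd(.data$auc),
      n_samples = dplyr::n_distinct(.data$sample),
      .groups = "drop"
    )
  keep <- stats_tbl$sd_auc >= min_sd & !is.na(stats_tbl$sd_auc) &
    stats_tbl$n_samples >= min_n
  stats_tbl$drug[keep]
}
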