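#' Read an in-frame codon alignment from FASTA
#'
#' Sequence names must match the tree's tip labels exactly when the
#' alignment is used with a tree. Gaps and ambiguity codes become missing
#' data; alignments whose length is not divisible by 3, or that contain
#' in-frame stop codons, are rejected.
#'
#' @param path FASTA file.
#' @param code A [genetic_code()].
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, code = std_genetic_code()) {
  dna <- ape::read.FASTA(path)
  chars <- toupper(vapply(as.character(dna), paste0, "", collapse = ""))
  chars <- gsub("[^ACGT]", "N", chars)  # ambiguity/gap -> missing nucleotide
  # any codon containing a non-ACGT character is treated as missing
  names(chars) <- names(dna)
  aln <- suppressWarnings(codon_alignment_missing(chars, code))
  aln
}

# like codon_alignment() but maps codons with N to NA before validation
codon_alignment_missing <- function(seqs, code) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length")
  if (lens[1] %% 3L != 0L) {
    stop("alignment length ", lens[1], " is not divisible by 3; ",
         "supply an in-frame codon alignment")
  }
  nsite <- lens[1] %/% 3L
  codmat <- t(vapply(seqs, function(s) {
    substring(s, seq(1, lens[1], by = 3), seq(3, lens[1], by = 3))
  }, character(nsite)))
  if (nsite == 1L) codmat <- matrix(codmat, ncol = 1,
                                    dimnames = list(names(seqs), NULL))
  codmat[grepl("N", codmat)] <- NA_character_
  codon_alignment(codmat, code)
}

#' Write a codon alignment (or simulation record) as FASTA
#'
#' @param x A [codon_alignment()] or `simulation_record`.
#' @param path Output file.
#' @export
write_codon_fasta <- function(x, path) {
  if (inherits(x, "simulation_record")) x <- x$alignment
  code <- attr(x, "code")
  lines <- character(0)
  for (i in seq_len(nrow(x))) {
    cods <- ifelse(is.na(x[i, ]), "NNN", code$codons[x[i, ]])
    lines <- c(lines, paste0(">", rownames(x)[i]), paste0(cods, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a branch mapping table as TSV with a manifest header
#'
#' Plain TSV preceded by `# key=value` comment lines echoing the run
#' configuration, so results are diff-able and replayable.
#'
#' @param res A `branch_dnds` data.frame (or any data.frame).
#' @param path Output file.
#' @param manifest Named list echoed as header comments.
#' @export
write_tsv_manifest <- function(res, path, manifest = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(manifest)) {
    writeLines(sprintf("# %s=%s", k, paste(manifest[[k]], collapse = ",")), con)
  }
  utils::write.table(as.data.frame(res), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_manifest()]
#' @param path Input file.
#' @return data.frame, with the manifest as attribute `"manifest"`.
#' @export
read_tsv_manifest <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  man <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", lines[h])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) man[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                          sep = "\t", header = TRUE)
  attr(df, "manifest") <- man
  df
}

#' Write a simulation record to a directory
#'
#' Emits the leaf alignment (FASTA), the scene tree (Newick), the
#' ground-truth per-branch event counts (TSV) and a JSON manifest with the
#' scene configuration sufficient for exact replay.
#'
#' @param record A `simulation_record`.
#' @param dir Output directory (created if needed).
#' @param manifest Extra manifest entries (e.g. the seed used).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(record, dir, manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_codon_fasta(record$alignment, file.path(dir, "alignment.fasta"))
  ape::write.tree(record$scene$tree, file.path(dir, "tree.nwk"))
  write_tsv_manifest(record$counts, file.path(dir, "truth.tsv"), manifest)
  jsonlite::write_json(
    c(manifest, list(
      nsites = ncol(record$alignment),
      taxa = rownames(record$alignment),
      models = lapply(record$scene$models, function(m)
        list(kappa = m$kappa, omega = m$omega,
             pi_gc = sum(m$pi[gc_mask_third(m$code)]))))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

gc_mask_third <- function(code) code$codon_nuc[, 3] %in% c(2L, 3L)

#' G+C content of a codon alignment
#'
#' @param aln A [codon_alignment()].
#' @param position Codon positions to include (default all three; `3` gives
#'   GC3).
#' @return Proportion of G or C among the counted nucleotides.
#' @export
gc_content <- function(aln, position = 1:3) {
  code <- attr(aln, "code")
  if (is.null(code)) code <- std_genetic_code()
  idx <- unclass(aln)[!is.na(aln)]
  nuc <- code$codon_nuc[idx, position, drop = FALSE]
  mean(nuc == 2L | nuc == 3L)
}
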