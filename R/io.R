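# Readers and writers for the pipeline's plain-text interchange formats:
# FASTA ORF sequences (via Biostrings), codon->rate TSVs, per-gene rate
# TSVs, density-target TSVs and sensitivity-profile TSVs.

#' Read ORF sequences and build gene models
#'
#' Reads a FASTA file of ORF nucleotide sequences, validates each (length
#' divisible by 3, leading ATG), trims a trailing stop codon when present,
#' and attaches per-codon decoding rates looked up from a codon rate
#' table. Initiation rates are not part of a FASTA file: genes receive the
#' placeholder `init_rate` (default 1) and are expected to go through
#' [calibrate_initiation_rate()].
#'
#' @param path FASTA file of ORF DNA sequences.
#' @param tdr_table Named numeric codon -> rate vector (e.g.
#'   [read_tdr_table()]).
#' @param footprint Ribosome footprint s.
#' @param init_rate Placeholder initiation rate.
#' @return Named list of [gene_model()]s.
#' @export
read_orf_fasta <- function(path, tdr_table, footprint = 9L, init_rate = 1) {
  seqs <- Biostrings::readDNAStringSet(path)
  genes <- lapply(seq_along(seqs), function(i) {
    id <- sub("\\s.*$", "", names(seqs)[i])
    sq <- toupper(as.character(seqs[[i]]))
    if (nchar(sq) %% 3 != 0) {
      stop("ORF '", id, "' length not divisible by 3")
    }
    codons <- substring(sq, seq(1, nchar(sq) - 2, 3), seq(3, nchar(sq), 3))
    if (codons[1] != "ATG") stop("ORF '", id, "' does not start with ATG")
    last <- codons[length(codons)]
    if (codon_to_aa(last) %in% "*" || last %in% c("TAA", "TAG", "TGA")) {
      codons <- codons[-length(codons)]
    }
    miss <- setdiff(unique(codons), names(tdr_table))
    if (length(miss)) {
      stop("ORF '", id, "' has codons missing from the rate table: ",
           paste(miss, collapse = ","))
    }
    gene_model(id, unname(tdr_table[codons]), init_rate, footprint, codons)
  })
  setNames(genes, vapply(genes, `[[`, "", "gene_id"))
}

#' Write gene models to FASTA
#'
#' Writes the codon sequences of a cohort as ORF nucleotide FASTA (no stop
#' codons; genes without sequences are refused).
#'
#' @param genes Named list of [gene_model()]s with sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(genes, path) {
  seqs <- vapply(genes, function(g) {
    if (is.null(g$codons)) stop("gene '", g$gene_id, "' has no sequence")
    paste(g$codons, collapse = "")
  }, "")
  xs <- Biostrings::DNAStringSet(seqs)
  names(xs) <- vapply(genes, `[[`, "", "gene_id")
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read a codon decoding-rate table
#'
#' TSV with columns `codon` and `rate` (codons/second), one row per sense
#' codon.
#'
#' @param path TSV path.
#' @return Named numeric vector codon -> rate.
#' @export
read_tdr_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "rate") %in% names(df)))
  if (any(df$rate <= 0)) stop("decoding rates must be positive")
  setNames(df$rate, toupper(df$codon))
}

#' Write a codon decoding-rate table
#' @param tdr_table Named numeric vector codon -> rate.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tdr_table <- function(tdr_table, path) {
  write_tsv(data.frame(codon = names(tdr_table), rate = unname(tdr_table)),
            path)
}

#' Read per-gene per-position decoding rates
#'
#' TSV with columns `gene_id`, `position`, `rate`; positions must form
#' `1..n` for each gene.
#'
#' @param path TSV path.
#' @param footprint Ribosome footprint s.
#' @param init_rate Placeholder initiation rate.
#' @return Named list of [gene_model()]s (no codon sequences).
#' @export
read_rate_tsv <- function(path, footprint = 9L, init_rate = 1) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "position", "rate") %in% names(df)))
  genes <- lapply(split(df, df$gene_id), function(d) {
    d <- d[order(d$position), ]
    if (!identical(as.integer(d$position), seq_len(nrow(d)))) {
      stop("positions for gene '", d$gene_id[1], "' are not 1..n")
    }
    gene_model(d$gene_id[1], d$rate, init_rate, footprint)
  })
  genes[order(names(genes))]
}

#' Read density targets for calibration
#'
#' TSV with columns `gene_id` and `target_ribosomes`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_density_targets <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "target_ribosomes") %in% names(df)))
  df
}

#' Write a sensitivity profile as TSV
#'
#' Long format: `gene_id`, `position`, `p`, `alpha`, `block_length`,
#' `sensitivity`, `se`, `ci`.
#'
#' @param profile A `sensitivity_profile` (or list of them).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  if (inherits(profile, "sensitivity_profile")) profile <- list(profile)
  df <- do.call(rbind, lapply(profile, as.data.frame))
  write_tsv(df, path)
}

#' Serialize a pi-matrix as long-format TSV
#' @param x A [pi_matrix()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pi_matrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "pi_matrix"))
  write_tsv(x$cells, path)
}

#' Build a simulation configuration from a YAML file
#'
#' Reads a YAML mapping whose keys are [sim_config()] arguments.
#'
#' @param path YAML path.
#' @return A [sim_config()].
#' @export
sim_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown sim_config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
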