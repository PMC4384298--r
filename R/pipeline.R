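#' Read a FASTQ file into a data.frame
#'
#' Plain or gzip-compressed 4-line FASTQ via Biostrings; CRLF line endings
#' are tolerated. Errors name the first malformed record.
#'
#' @param path FASTQ path (`.gz` allowed).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTQ file: ", path,
                               call. = FALSE)
  res <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    data.frame(id = sub("\r$", "", names(x)),
               seq = unname(as.character(x)),
               qual = unname(as.character(S4Vectors::mcols(x)$qualities)),
               row.names = NULL, stringsAsFactors = FALSE)
  }, error = function(e) stop("malformed FASTQ in '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  bad <- nchar(res$seq) != nchar(res$qual)
  if (any(bad)) {
    stop("malformed FASTQ in '", path, "': record '", res$id[bad][1L],
         "' has mismatched sequence and quality lengths", call. = FALSE)
  }
  res
}

#' Write records to a FASTQ file
#'
#' Round-trips [read_fastq()] output losslessly (LF line endings, gzip when
#' the path ends in `.gz`).
#'
#' @param records data.frame with `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(records)))
  bad <- nchar(records$seq) != nchar(records$qual)
  if (any(bad)) stop("record '", records$id[bad][1L],
                     "': sequence and quality lengths differ", call. = FALSE)
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(records$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Score, decode and extract a batch of reads
#'
#' The per-read core of the pipeline: forward/backward scoring, posterior
#' labeling, optimal-accuracy decoding and extraction against a fixed
#' architecture and threshold.
#'
#' @param records data.frame with `id`, `seq`, `qual` (see [read_fastq()]).
#' @param hmm Compiled `profile_hmm` for `arch`.
#' @param arch The `read_architecture`.
#' @param threshold Extraction-quality acceptance threshold.
#' @return List of `labeled_read` objects.
#' @export
extract_reads <- function(records, hmm, arch, threshold = 0) {
  lapply(seq_len(nrow(records)), function(i) {
    rec <- list(id = records$id[[i]], seq = records$seq[[i]],
                qual = records$qual[[i]])
    sc <- score_read(hmm, rec$seq)
    post <- posterior_labels(sc$matrices, hmm)
    labels <- optimal_accuracy_decode(post, arch)
    extract_read(rec, labels, arch, sc, threshold)
  })
}

#' Pick the architecture that best explains a read sample
#'
#' Each candidate architecture is compiled and the mean per-read log-odds
#' `log P(x|M) - log P(x|R)` over the sampled reads is computed with the
#' forward algorithm; the architecture with the largest mean wins (first in
#' file order on ties).
#'
#' @param reads Character vector of read sequences (a sample of the input;
#'   only the first `sample_n` are used).
#' @param lib An `architecture_library` from [load_architecture_file()], or
#'   a list of `read_architecture` objects.
#' @param err,bg Model parameters passed to [assemble_global_hmm()].
#' @param sample_n Maximum number of reads scored per architecture.
#' @return List with `best` (a `read_architecture`) and `scores` (named
#'   mean log-odds per architecture).
#' @export
detect_architecture <- function(reads, lib, err = error_model(),
                                bg = background_model(), sample_n = 1000L) {
  stopifnot(length(lib) >= 1L)
  reads <- utils::head(reads, sample_n)
  if (length(reads) == 0L) stop("no reads to detect from", call. = FALSE)
  scores <- vapply(lib, function(arch) {
    hmm <- assemble_global_hmm(arch, err, bg)
    mean(vapply(reads, function(x) {
      hmm_forward(hmm, x)$logPxM - background_score(x, bg)
    }, 0, USE.NAMES = FALSE))
  }, 0)
  nm <- vapply(lib, `[[`, "", "name")
  names(scores) <- nm
  list(best = lib[[which.max(scores)]], scores = scores)
}

#' Run the full extraction pipeline on a FASTQ file
#'
#' Streams raw reads through architecture resolution (auto-detection when a
#' library is given), background estimation, threshold calibration, HMM
#' scoring and decoding, contaminant and low-complexity filtering, and
#' demultiplexed output. Deterministic given `seed`; `n_threads` is part of
#' the configuration contract but never changes results (the implementation
#' is single-threaded).
#'
#' Outputs under `out_prefix`: one `<prefix>_BC_<seq>_R1.fastq` per barcode
#' (or `<prefix>_extracted_R1.fastq` without barcodes) with
#' `;BC:<seq>;UMI:<code>;Q:<q>` appended to accepted read names, an
#' `<prefix>_un_R1.fastq` with rejected reads (reason appended), and
#' `<prefix>_report.tsv`.
#'
#' @param input Path to the R1 FASTQ file (optionally gzipped).
#' @param arch A `read_architecture` (exclusive with `arch_file`).
#' @param arch_file Path to an architecture library file; the best-matching
#'   architecture is auto-detected.
#' @param out_prefix Output path prefix.
#' @param input2 Optional R2 FASTQ for paired-end input. R2 follows R1's
#'   accept/reject decision and barcode; with `arch2` given, decisions are
#'   made jointly by summing the two mates' log-odds and multiplying their
#'   barcode confidences.
#' @param arch2 Optional architecture for R2.
#' @param threshold Fixed extraction-quality threshold; `NULL` (default)
#'   calibrates it automatically via [calibrate_threshold()].
#' @param err An [error_model()].
#' @param bg A [background_model()]; `NULL` estimates it from the first
#'   100,000 input reads.
#' @param ref Optional contaminant FASTA path or named character vector.
#' @param max_edits Contaminant edit-distance budget.
#' @param dust DUST threshold (0 disables the low-complexity filter).
#' @param seed Seed for calibration emission.
#' @param detect_sample Reads sampled for architecture detection.
#' @param calibration_n Reads emitted per class during calibration.
#' @param n_threads Accepted for configuration compatibility; results are
#'   identical for any value.
#' @return A `run_report` (invisibly printable): chosen architecture and
#'   threshold, per-barcode accepted counts, rejection counts by reason,
#'   detection scores, contaminant counts, output paths.
#' @export
run_extraction <- function(input, arch = NULL, arch_file = NULL,
                           out_prefix = "hmmdemux", input2 = NULL,
                           arch2 = NULL, threshold = NULL,
                           err = error_model(), bg = NULL, ref = NULL,
                           max_edits = 3L, dust = 100, seed = 42L,
                           detect_sample = 1000L, calibration_n = 10000L,
                           n_threads = 1L) {
  if (is.null(arch) == is.null(arch_file)) {
    stop("exactly one of 'arch' and 'arch_file' must be given",
         call. = FALSE)
  }
  records <- read_fastq(input)
  records2 <- NULL
  if (!is.null(input2)) {
    records2 <- read_fastq(input2)
    id1 <- sub("/[12]$", "", sub(" .*$", "", records$id))
    id2 <- sub("/[12]$", "", sub(" .*$", "", records2$id))
    if (nrow(records2) != nrow(records) || !all(id1 == id2)) {
      stop("paired FASTQ files are desynchronized", call. = FALSE)
    }
  }
  if (is.null(bg)) bg <- estimate_background(records$seq)

  detection_scores <- NULL
  if (!is.null(arch_file)) {
    lib <- load_architecture_file(arch_file)
    det <- detect_architecture(records$seq, lib, err, bg,
                               sample_n = detect_sample)
    arch <- det$best
    detection_scores <- det$scores
  }
  hmm <- assemble_global_hmm(arch, err, bg)
  hmm2 <- if (!is.null(arch2)) assemble_global_hmm(arch2, err, bg) else NULL

  insert_len <- max(5L, round(stats::median(nchar(records$seq))) -
                      arch_fixed_length(arch))
  calib <- NULL
  if (is.null(threshold)) {
    calib <- calibrate_threshold(hmm, n = calibration_n, seed = seed,
                                 read_length = insert_len)
    threshold <- calib$threshold
  }

  labeled <- vector("list", nrow(records))
  labeled2 <- if (!is.null(hmm2)) vector("list", nrow(records)) else NULL
  for (i in seq_len(nrow(records))) {
    rec <- list(id = records$id[[i]], seq = records$seq[[i]],
                qual = records$qual[[i]])
    sc <- score_read(hmm, rec$seq)
    if (!is.null(hmm2)) {
      sc2 <- score_read(hmm2, records2$seq[[i]])
      joint <- extraction_quality(
        sc$logPxM + sc2$logPxM, sc$logPxR + sc2$logPxR, sc$V * sc2$V)
      sc$p_error <- joint$p_error
      sc$q <- joint$q
      if (identical(sc2$best_barcode, "background"))
        sc$best_barcode <- "background"
      post2 <- posterior_labels(sc2$matrices, hmm2)
      lab2 <- optimal_accuracy_decode(post2, arch2)
      labeled2[[i]] <- extract_read(
        list(id = records2$id[[i]], seq = records2$seq[[i]],
             qual = records2$qual[[i]]), lab2, arch2, sc, threshold)
    }
    post <- posterior_labels(sc$matrices, hmm)
    labels <- optimal_accuracy_decode(post, arch)
    labeled[[i]] <- extract_read(rec, labels, arch, sc, threshold)
  }

  accepted <- vapply(labeled, `[[`, TRUE, "accepted")
  reasons <- vapply(labeled, function(l)
    if (is.na(l$reason)) "" else l$reason, "")

  # post-extraction filters on the accepted reads' extracted insert
  contaminant_counts <- NULL
  if (!is.null(ref) && any(accepted)) {
    idx <- which(accepted)
    seqs <- stats::setNames(
      vapply(labeled[idx], `[[`, "", "read_seq"),
      vapply(labeled[idx], `[[`, "", "source"))
    fc <- filter_contaminants(seqs, ref, max_k = max_edits)
    hit_idx <- idx[names(seqs) %in% fc$hits$id]
    accepted[hit_idx] <- FALSE
    reasons[hit_idx] <- "contaminant"
    contaminant_counts <- fc$counts
  }
  if (dust > 0 && any(accepted)) {
    idx <- which(accepted)
    flagged <- vapply(idx, function(i)
      dust_score(labeled[[i]]$read_seq, threshold = dust)$flagged, TRUE)
    accepted[idx[flagged]] <- FALSE
    reasons[idx[flagged]] <- "low complexity"
  }
  for (i in seq_along(labeled)) {
    labeled[[i]]$accepted <- accepted[[i]]
    labeled[[i]]$reason <- if (accepted[[i]]) NA_character_ else reasons[[i]]
  }

  write_outputs <- function(labeled_x, records_x, mate) {
    paths <- character()
    bc <- vapply(labeled_x, function(l)
      if (is.na(l$barcode)) "" else l$barcode, "")
    groups <- if (any(nzchar(bc[accepted]))) unique(bc[accepted]) else ""
    for (g in sort(groups)) {
      sel <- which(accepted & bc == g)
      if (length(sel) == 0L) next
      tag <- if (nzchar(g)) paste0("_BC_", g) else "_extracted"
      path <- paste0(out_prefix, tag, "_R", mate, ".fastq")
      out <- data.frame(
        id = vapply(sel, function(i) paste0(
          labeled_x[[i]]$source, ";BC:", if (nzchar(bc[[i]])) bc[[i]] else ".",
          ";UMI:", if (is.na(labeled_x[[i]]$umi_code)) "."
                   else format(labeled_x[[i]]$umi_code, scientific = FALSE),
          ";Q:", sprintf("%.2f", labeled_x[[i]]$q)), ""),
        seq = vapply(labeled_x[sel], `[[`, "", "read_seq"),
        qual = vapply(labeled_x[sel], `[[`, "", "read_qual"),
        stringsAsFactors = FALSE)
      write_fastq(out, path)
      paths <- c(paths, path)
    }
    un <- which(!accepted)
    un_path <- paste0(out_prefix, "_un_R", mate, ".fastq")
    write_fastq(data.frame(
      id = paste0(records_x$id[un], ";reason:", reasons[un]),
      seq = records_x$seq[un], qual = records_x$qual[un],
      stringsAsFactors = FALSE), un_path)
    c(paths, un_path)
  }
  paths <- write_outputs(labeled, records, 1L)
  if (!is.null(records2)) {
    lab2 <- if (!is.null(labeled2)) labeled2 else lapply(
      seq_len(nrow(records2)), function(i) {
        l <- labeled[[i]]
        l$read_seq <- records2$seq[[i]]
        l$read_qual <- records2$qual[[i]]
        l$source <- records2$id[[i]]
        l
      })
    for (i in seq_along(lab2)) lab2[[i]]$accepted <- accepted[[i]]
    paths <- c(paths, write_outputs(lab2, records2, 2L))
  }

  bc_calls <- vapply(labeled, function(l)
    if (is.na(l$barcode)) "(no barcode)" else l$barcode, "")
  accepted_by_barcode <- table(bc_calls[accepted])
  rejected_by_reason <- table(reasons[!accepted])

  report <- structure(list(
    input = input, n_input = nrow(records),
    architecture = arch$name,
    architecture_spec = paste(format(arch), collapse = " "),
    detection_scores = detection_scores,
    threshold = threshold,
    calibration = if (!is.null(calib))
      calib[c("sensitivity", "specificity", "n_model", "n_random", "seed")]
      else NULL,
    n_accepted = sum(accepted),
    accepted_by_barcode = accepted_by_barcode,
    rejected_by_reason = rejected_by_reason,
    contaminant_counts = contaminant_counts,
    insert_length = insert_len,
    outputs = paths,
    labeled = labeled), class = "run_report")
  stopifnot(report$n_input == report$n_accepted + sum(rejected_by_reason))
  write_report(report, paste0(out_prefix, "_report.tsv"))
  report
}

#' Write a run report as flat key-value TSV
#'
#' @param report A `run_report` from [run_extraction()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  kv <- c(input = report$input, n_input = report$n_input,
          architecture = report$architecture,
          architecture_spec = report$architecture_spec,
          threshold = sprintf("%.6g", report$threshold),
          n_accepted = report$n_accepted)
  if (!is.null(report$calibration)) {
    kv <- c(kv, calibration_sensitivity =
              sprintf("%.6g", report$calibration$sensitivity),
            calibration_specificity =
              sprintf("%.6g", report$calibration$specificity))
  }
  if (!is.null(report$detection_scores)) {
    kv <- c(kv, stats::setNames(
      sprintf("%.6g", report$detection_scores),
      paste0("detection_score.", names(report$detection_scores))))
  }
  kv <- c(kv, stats::setNames(as.integer(report$accepted_by_barcode),
                              paste0("accepted.",
                                     names(report$accepted_by_barcode))))
  kv <- c(kv, stats::setNames(as.integer(report$rejected_by_reason),
                              paste0("rejected.",
                                     names(report$rejected_by_reason))))
  if (!is.null(report$contaminant_counts)) {
    kv <- c(kv, stats::setNames(as.integer(report$contaminant_counts),
                                paste0("contaminant.",
                                       names(report$contaminant_counts))))
  }
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report for", x$input, "\n")
  cat("  architecture:", x$architecture, "(", x$architecture_spec, ")\n")
  cat(sprintf("  threshold: q >= %.3f\n", x$threshold))
  cat("  input reads:", x$n_input, " accepted:", x$n_accepted, "\n")
  if (length(x$accepted_by_barcode)) {
    cat("  accepted by barcode:\n")
    for (nm in names(x$accepted_by_barcode))
      cat("    ", nm, ":", x$accepted_by_barcode[[nm]], "\n")
  }
  if (length(x$rejected_by_reason)) {
    cat("  rejected by reason:\n")
    for (nm in names(x$rejected_by_reason))
      cat("    ", nm, ":", x$rejected_by_reason[[nm]], "\n")
  }
  invisible(x)
}
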