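#' Read ms/discoal-style haplotype text
#'
#' Parses replicate blocks ("//", `segsites: S`, `positions: ...`, one 0/1
#' string per haplotype). Relative positions on `[0, 1)` are scaled by `L`.
#'
#' @param x file path or character vector of lines.
#' @param L fragment length in bp used to scale relative positions.
#' @return list of [hap_window()] (degenerate zero-segsite replicates are
#'   returned as `NULL` entries with a warning).
#' @export
read_ms_format <- function(x, L = 1e5) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  starts <- grep("^//", lines)
  if (!length(starts)) stop("no replicate blocks ('//') found")
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (r in seq_along(starts)) {
    block <- lines[(bounds[r] + 1L):(bounds[r + 1L] - 1L)]
    segline <- grep("^segsites:", block, value = TRUE)
    if (!length(segline)) stop("malformed block (no segsites) in replicate ", r)
    S <- as.integer(sub("^segsites:\\s*", "", segline[1]))
    if (S == 0L) {
      warning("replicate ", r, " has zero segregating sites")
      next
    }
    posline <- grep("^positions:", block, value = TRUE)
    pos <- as.numeric(strsplit(sub("^positions:\\s*", "", posline[1]),
                               "\\s+")[[1]])
    hap_lines <- block[grepl("^[01]+$", block)]
    if (!length(hap_lines)) stop("malformed block (no haplotypes) in replicate ", r)
    mat <- do.call(rbind, lapply(strsplit(hap_lines, ""), as.integer))
    if (ncol(mat) != S) stop("haplotype width != segsites in replicate ", r)
    pos <- pos * L
    pos <- pos + cumsum(c(0, diff(pos) <= 0)) * 1e-9
    out[[r]] <- hap_window(mat, pos, span = c(0, L), drop_monomorphic = FALSE)
  }
  out
}

#' Write haplotype windows in ms format
#'
#' @param wins list of [hap_window()] (or `labeled_case`s).
#' @param path output file.
#' @param L fragment length for rescaling positions to `[0, 1)`.
#' @return `path`, invisibly.
#' @export
write_ms_format <- function(wins, path, L = 1e5) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ms-format export", "", ""), con)
  for (w in wins) {
    if (inherits(w, "labeled_case")) w <- w$haplotypes
    writeLines("//", con)
    writeLines(paste0("segsites: ", ncol(w$matrix)), con)
    writeLines(paste("positions:",
                     paste(formatC(w$positions / L, digits = 17, format = "g"),
                           collapse = " ")), con)
    writeLines(apply(w$matrix, 1, paste, collapse = ""), con)
  }
  invisible(path)
}

#' Read phased biallelic haplotypes from a VCF
#'
#' Splits phased diploid genotypes into haplotype columns. Polarization uses
#' the `AA` INFO ancestral-allele annotation when present; otherwise the
#' data are folded to major/minor coding with a warning (the
#' polarization-dependent statistics then read major-allele background vs
#' minor-allele foreground).
#'
#' @param path VCF file (uncompressed or gzipped; requires the `vcfR`
#'   package).
#' @param region optional `c(start, end)` bp filter.
#' @return a [hap_window()] plus attributes `n_skipped` (multiallelic or
#'   unphased records) and `folded`.
#' @export
read_vcf_phased <- function(path, region = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_phased requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  pos <- as.numeric(fix[, "POS"])
  if (is.unsorted(pos)) stop("VCF is not position-sorted")
  gt <- vcfR::extract.gt(v, element = "GT")
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  phased <- apply(gt, 1, function(g) all(grepl("\\|", g)))
  keep <- biallelic & phased
  if (!is.null(region)) keep <- keep & pos >= region[1] & pos < region[2]
  n_skipped <- sum(!keep)
  gt <- gt[keep, , drop = FALSE]; pos <- pos[keep]; fix <- fix[keep, , drop = FALSE]
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow(gt))
  hap <- rbind(t(a1), t(a2))                 # 2 haplotypes per sample
  info <- fix[, "INFO"]
  aa <- sub(".*AA=([ACGTacgt]).*", "\\1", info)
  has_aa <- grepl("AA=", info)
  folded <- !all(has_aa)
  if (!folded) {
    flip <- toupper(aa) == toupper(fix[, "ALT"])
    hap[, flip] <- 1L - hap[, flip]
  } else {
    warning("no ancestral-allele (AA) annotation: folding to major/minor coding")
    freq <- colMeans(hap)
    flip <- freq > 0.5
    hap[, flip] <- 1L - hap[, flip]
  }
  dedup <- c(TRUE, diff(pos) > 0)
  win <- hap_window(hap[, dedup, drop = FALSE], pos[dedup])
  attr(win, "n_skipped") <- n_skipped
  attr(win, "folded") <- folded
  win
}

#' Fingerprint a configuration object
#'
#' MD5 of the object's serialization; recorded in output headers so a
#' prediction file can be traced to the exact run configuration.
#' @param config any serializable object.
#' @return hex string.
#' @export
config_fingerprint <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Write prediction records to TSV
#'
#' One row per fragment, sorted by chrom then start, 0-based half-open
#' coordinates, full 5-class probability vector, argmax label and domain
#' score; the header records a config fingerprint.
#'
#' @param records data.frame with columns `chrom`, `start`, `end`,
#'   `p_hard`, `p_linked_hard`, `p_soft`, `p_linked_soft`, `p_neutral`,
#'   `label`, `domain_score`.
#' @param path output path.
#' @param fingerprint config fingerprint string.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path, fingerprint = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sweepdann predictions; config=", fingerprint), con)
  if (nrow(records)) {
    records <- records[order(records$chrom, records$start), ]
  }
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a predictions TSV
#' @param path file written by [write_predictions()].
#' @return data.frame of prediction records.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Build prediction records from model output
#'
#' @param probs 5 x N probability matrix ([sweep_classes()] row order).
#' @param domain length-N domain scores.
#' @param coords data.frame `chrom`, `start`, `end` per fragment.
#' @return prediction-record data.frame for [write_predictions()].
#' @export
prediction_records <- function(probs, domain, coords) {
  stopifnot(ncol(probs) == nrow(coords))
  cls <- sweep_classes()
  out <- cbind(coords,
               stats::setNames(as.data.frame(t(probs)), paste0("p_", cls)))
  out$label <- cls[max.col(t(probs), ties.method = "first")]
  out$domain_score <- domain
  out
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> featurize -> train (transductive, ensembled) -> predict ->
#' evaluate, with stage artifacts cached under `cache_dir` so a rerun only
#' redoes missing stages.
#'
#' @param source_params,target_params [scenario_params()] for the two
#'   domains (`target_params` may equal `source_params` for the matched
#'   scenario).
#' @param per_class `c(train, validation, test)` cases per class.
#' @param spec a [fragment_spec()].
#' @param config a [dann_config()].
#' @param seed master seed, expanded deterministically into per-stage
#'   streams.
#' @param cache_dir optional directory for stage artifacts (RDS).
#' @return list `eval` (accuracy, per-class accuracy, confusion, ROC/AUCs,
#'   confidence, domain diagnostics), `models`, `datasets`.
#' @export
run_end_to_end <- function(source_params, target_params = source_params,
                           per_class = c(train = 50, validation = 15, test = 15),
                           spec = fragment_spec(n = 32, k = 10, m = 32, L = source_params$L),
                           config = dann_config(M = 1L, epochs = 15L),
                           seed = 1L, cache_dir = NULL) {
  stage <- function(name, expr) {
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(cache_dir, paste0(name, ".rds"))
      if (file.exists(f)) return(readRDS(f))
      val <- force(expr)
      saveRDS(val, f)
      return(val)
    }
    force(expr)
  }
  data <- stage("data", {
    cases <- generate_cases(source_params, sum(per_class), seed = seed)
    splits <- make_splits(cases, per_class, seed = seed + 1L)
    target <- generate_cases(target_params, per_class[["test"]], seed = seed * 3L + 7L)
    list(splits = splits, target = target)
  })
  feats <- stage("features", {
    train <- featurize_cases(data$splits$train, spec)
    list(train = train,
         val = featurize_cases(data$splits$validation, spec, scale = train$scale),
         test = featurize_cases(data$splits$test, spec, scale = train$scale),
         target = featurize_cases(data$target, spec, scale = train$scale))
  })
  models <- stage("models", {
    dann_train_ensemble(feats$train$x, feats$train$y, target = feats$target$x,
                        config = config,
                        val = list(x = feats$val$x, y = feats$val$y))
  })
  pred_test <- ensemble_predict(models, feats$test$x)
  pred_target <- ensemble_predict(models, feats$target$x)
  cls <- sweep_classes()
  test_labels <- as.character(feats$test$y)
  pred_labels <- cls[max.col(t(pred_test$probs), ties.method = "first")]
  conf <- confusion_5class(pred_labels, test_labels)
  roc <- model_sweep_roc(pred_test$probs, test_labels)
  tgt_truth <- as.character(feats$target$y)
  tgt_labels <- cls[max.col(t(pred_target$probs), ties.method = "first")]
  eval <- list(
    accuracy = mean(pred_labels == test_labels),
    per_class_accuracy = conf$per_class_accuracy,
    confusion = conf,
    auc_overall = roc$overall$auc, auc_hard = roc$hard$auc,
    auc_soft = roc$soft$auc,
    confidence = prediction_confidence(pred_test$probs),
    target_accuracy = if (!is.null(feats$target$y))
      mean(tgt_labels == tgt_truth) else NA_real_,
    domain = domain_score_histogram(pred_target$domain))
  list(eval = eval, models = models,
       datasets = list(features = feats, data = data))
}
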