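#' Column map for vendor quantification reports
#'
#' Maps the six canonical roles (protein, precursor, fragment, condition,
#' replicate, quantity) to the column names of a long-format fragment-level
#' report.  Shipped presets cover the common export styles; all are
#' best-effort and user-overridable.
#'
#' @param protein,precursor,fragment,condition,replicate,quantity Column
#'   names in the report header.
#' @return An object of class `"column_map"` (named character vector).
#' @export
column_map <- function(protein = "protein", precursor = "precursor",
                       fragment = "fragment", condition = "condition",
                       replicate = "replicate", quantity = "quantity") {
  m <- c(protein = protein, precursor = precursor, fragment = fragment,
         condition = condition, replicate = replicate, quantity = quantity)
  if (any(!nzchar(m)) || anyNA(m)) stop("all six roles must be mapped")
  structure(m, class = "column_map")
}

#' @rdname column_map
#' @param style One of `"canonical"` (the simulator's own writer),
#'   `"spectronaut"`, `"maxquant"`, `"skyline"`.
#' @export
default_column_map <- function(style = c("canonical", "spectronaut",
                                         "maxquant", "skyline")) {
  style <- match.arg(style)
  switch(style,
    canonical = column_map(),
    spectronaut = column_map(
      protein = "PG.ProteinGroups", precursor = "EG.PrecursorId",
      fragment = "F.FrgIon", condition = "R.Condition",
      replicate = "R.Replicate", quantity = "F.PeakArea"),
    maxquant = column_map(
      protein = "Proteins", precursor = "Modified.sequence",
      fragment = "Fragment", condition = "Experiment",
      replicate = "Replicate", quantity = "Intensity"),
    skyline = column_map(
      protein = "Protein.Name", precursor = "Peptide.Modified.Sequence",
      fragment = "Fragment.Ion", condition = "Condition",
      replicate = "Replicate.Name", quantity = "Area")
  )
}

#' Read a long-format fragment quantification report
#'
#' Reads a delimited text report (tab or comma, auto-detected from the
#' header line) and maps it to the canonical fragment table.  Rows with
#' missing or non-positive quantities are dropped (counts reported via
#' message and the `"dropped"` attribute); duplicate (precursor, fragment,
#' condition, replicate) combinations are an error.
#'
#' @param path Path to the report file.
#' @param map A [column_map()] (default: canonical columns).
#' @return Canonical fragment table `data.frame` with columns `protein`,
#'   `precursor`, `fragment`, `condition`, `replicate`, `quantity`,
#'   `log10_quantity`, and attribute `dropped` (number of removed rows).
#' @export
read_fragment_report <- function(path, map = default_column_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE,
                           comment.char = "", quote = "\"")
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols))
    stop("mapped column(s) absent from report: ",
         paste(missing_cols, collapse = ", "))
  qty <- raw[[map[["quantity"]]]]
  if (!is.numeric(qty)) {
    qty_num <- suppressWarnings(as.numeric(qty))
    bad <- which(is.na(qty_num) & !is.na(qty) & nzchar(trimws(qty)) &
                   toupper(trimws(qty)) != "NA")
    if (length(bad))
      stop("unparseable quantity value(s), e.g. row ", bad[1L], ": ",
           qty[bad[1L]])
    qty <- qty_num
  }
  tab <- data.frame(
    protein = as.character(raw[[map[["protein"]]]]),
    precursor = as.character(raw[[map[["precursor"]]]]),
    fragment = raw[[map[["fragment"]]]],
    condition = raw[[map[["condition"]]]],
    replicate = raw[[map[["replicate"]]]],
    quantity = qty,
    stringsAsFactors = FALSE
  )
  keep <- !is.na(tab$quantity) & tab$quantity > 0
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " row(s) with missing or non-positive quantity dropped")
  tab <- tab[keep, , drop = FALSE]
  key <- paste(tab$precursor, tab$fragment, tab$condition, tab$replicate,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), c("precursor", "fragment", "condition",
                                  "replicate")]
    stop("duplicate (precursor, fragment, condition, replicate) rows, e.g.: ",
         paste(unlist(dup[1L, ]), collapse = " / "))
  }
  tab$log10_quantity <- log10(tab$quantity)
  rownames(tab) <- NULL
  attr(tab, "dropped") <- dropped
  tab
}

#' Write a fragment table as a tab-separated report
#'
#' Writes the canonical long format (`protein`, `precursor`, `fragment`,
#' `condition`, `replicate`, `quantity`) with quantities in full double
#' precision (17 significant digits), so a write/read round trip reproduces
#' the log10 quantities bit-identically.
#'
#' @param table Fragment table `data.frame` or a `fragment_sim`.
#' @param path Output path.
#' @param latents_path Optional sidecar path; for a `fragment_sim` input,
#'   writes the per-(condition, peptide) latent truths (`mu_p`, `zeta_cp`)
#'   for benchmark use.
#' @return `path`, invisibly.
#' @export
write_fragment_report <- function(table, path, latents_path = NULL) {
  sim <- NULL
  if (inherits(table, "fragment_sim")) { sim <- table; table <- table$table }
  cols <- c("protein", "precursor", "fragment", "condition", "replicate",
            "quantity")
  stopifnot(all(cols %in% names(table)))
  out <- table[cols]
  out$quantity <- sprintf("%.17g", out$quantity)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(latents_path)) {
    if (is.null(sim))
      stop("latent sidecar requires a fragment_sim input")
    P <- sim$params$n_peptides; C <- sim$params$n_conditions
    lat <- data.frame(
      precursor = rep(sprintf("pep%05d", seq_len(P)), each = C),
      condition = rep(seq_len(C), P),
      mu_p = rep(sim$latents$mu_p, each = C),
      zeta_cp = as.numeric(sim$latents$zeta_cp),
      stringsAsFactors = FALSE
    )
    lat$mu_p <- sprintf("%.17g", lat$mu_p)
    lat$zeta_cp <- sprintf("%.17g", lat$zeta_cp)
    utils::write.table(lat, latents_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Select complete peptide blocks for a two-condition comparison
#'
#' Keeps precursors observed with exactly `n_fragments` fragments (the same
#' fragment set) in every (condition, replicate) run of the comparison and
#' with equal replicate counts in both conditions; replicates are paired
#' across conditions by sorted label order.  Everything else is skipped with
#' a per-reason summary (attribute `skipped`).
#'
#' @param table Canonical fragment table.
#' @param conditions Length-2 vector of condition levels to compare
#'   (default: first two levels in sorted order).
#' @param n_fragments Required fragment count I.
#' @return List of [peptide_block()] objects, with attribute `skipped`
#'   (named integer vector of skip reasons).  Zero qualifying peptides is an
#'   error.
#' @export
select_complete_blocks <- function(table, conditions = NULL,
                                   n_fragments = 3L) {
  tab <- as.data.frame(table)
  if (!"log10_quantity" %in% names(tab))
    tab$log10_quantity <- log10(tab$quantity)
  levels_all <- sort(unique(as.character(tab$condition)))
  if (is.null(conditions)) {
    if (length(levels_all) < 2L) stop("need two condition levels")
    conditions <- levels_all[1:2]
  }
  conditions <- as.character(conditions)
  if (length(conditions) != 2L || conditions[1L] == conditions[2L])
    stop("conditions must name two distinct levels")
  if (!all(conditions %in% levels_all))
    stop("condition level(s) not present: ",
         paste(setdiff(conditions, levels_all), collapse = ", "))
  tab <- tab[as.character(tab$condition) %in% conditions, , drop = FALSE]
  I <- as.integer(n_fragments)
  skipped <- c(incomplete = 0L, unequal_replicates = 0L,
               missing_condition = 0L)
  blocks <- list()
  idx_by_pep <- split(seq_len(nrow(tab)), tab$precursor)
  for (pep in unique(tab$precursor)) {
    sub <- tab[idx_by_pep[[pep]], , drop = FALSE]
    conds <- as.character(sub$condition)
    if (!all(conditions %in% conds)) {
      skipped["missing_condition"] <- skipped["missing_condition"] + 1L
      next
    }
    reps1 <- sort(unique(as.character(sub$replicate[conds == conditions[1L]])))
    reps2 <- sort(unique(as.character(sub$replicate[conds == conditions[2L]])))
    if (length(reps1) != length(reps2)) {
      skipped["unequal_replicates"] <- skipped["unequal_replicates"] + 1L
      next
    }
    R <- length(reps1)
    if (R < 2L) {
      skipped["incomplete"] <- skipped["incomplete"] + 1L
      next
    }
    frag_sets <- tapply(as.character(sub$fragment),
                        paste(conds, sub$replicate, sep = "\r"),
                        function(f) paste(sort(f), collapse = "\r"))
    ref <- paste(sort(unique(as.character(sub$fragment))), collapse = "\r")
    n_frag <- length(unique(as.character(sub$fragment)))
    if (n_frag != I || any(frag_sets != ref) ||
        length(frag_sets) != 2L * R) {
      skipped["incomplete"] <- skipped["incomplete"] + 1L
      next
    }
    frags <- sort(unique(as.character(sub$fragment)))
    X <- matrix(NA_real_, R, 2L * I)
    for (ci in 1:2) {
      reps <- if (ci == 1L) reps1 else reps2
      for (ri in seq_len(R)) {
        rows <- conds == conditions[ci] &
          as.character(sub$replicate) == reps[ri]
        vals <- sub$log10_quantity[rows][match(frags,
                                               as.character(sub$fragment[rows]))]
        X[ri, (ci - 1L) * I + seq_len(I)] <- vals
      }
    }
    blocks[[pep]] <- peptide_block(X, I, peptide = pep)
  }
  if (length(blocks) == 0L)
    stop("zero qualifying peptides (skipped: ",
         paste(names(skipped), skipped, sep = "=", collapse = ", "), ")")
  attr(blocks, "skipped") <- skipped
  blocks
}

#' Write per-peptide test results
#'
#' Tab-separated with stable column order (`peptide`, `method`, `estimate`,
#' `se`, `statistic`, `df`, `p_value`, `flags`, plus any diagnostic
#' columns); numbers in full double precision, infinite degrees-of-freedom
#' serialized as the literal token `Inf`.  Round-trips through
#' [read_results()].
#'
#' @param results `data.frame` from [run_differential_tests()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  res <- as.data.frame(results)
  core <- c("peptide", "method", "estimate", "se", "statistic", "df",
            "p_value", "flags")
  stopifnot(all(core %in% c(names(res), "flags")))
  if (!"flags" %in% names(res)) res$flags <- ""
  res <- res[c(core, setdiff(names(res), core))]
  for (nm in names(res)) {
    if (is.numeric(res[[nm]]))
      res[[nm]] <- ifelse(is.finite(res[[nm]]),
                          sprintf("%.17g", res[[nm]]),
                          as.character(res[[nm]]))
  }
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  res <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = "NA",
                           colClasses = c(peptide = "character",
                                          method = "character",
                                          flags = "character"))
  for (nm in setdiff(names(res), c("peptide", "method", "flags")))
    res[[nm]] <- as.numeric(res[[nm]])
  res$flags[is.na(res$flags)] <- ""
  res
}

#' Read a flat key-value configuration file
#'
#' One `key = value` (or `key: value`) pair per line; `#` starts a comment.
#' Values are parsed as numeric scalars or comma-separated numeric vectors
#' when possible, otherwise kept as strings.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("unparseable config line: ", ln)
    key <- trimws(m[2L]); val <- trimws(m[3L])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) {
      if (length(nums) == 1L) nums else nums
    } else val
  }
  out
}
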