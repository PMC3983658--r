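# Readers and writers for the five standard inputs. All files are
# tab-delimited UTF-8 with "NA" for missing values. Coordinates are 0-based
# half-open (BED-native) throughout; see from_one_based() for converting
# 1-based inclusive inputs at the boundary.

ORI_STATUSES <- c("confirmed", "likely", "dubious")

#' Read a gene annotation BED file
#'
#' Expects BED with at least 3 columns (`chrom`, `start`, `end`); column 4 is
#' the gene id and column 6 the strand. When the strand column is absent all
#' genes are taken as `+` with a warning. Input order is preserved.
#'
#' @param path Path to a tab-delimited BED file without header.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes <- function(path) {
  raw <- readLines(path)
  keep <- which(nzchar(raw))
  lines <- raw[keep]
  if (length(lines) == 0) {
    warn("empty gene file; returning an empty gene table")
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3) {
    abort("BED input needs at least 3 columns (chrom, start, end)",
          class = "repcycle_data_error")
  }
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, character(1))
  chrom <- col(1)
  start_chr <- col(2)
  end_chr <- col(3)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad <- which(is.na(start) | is.na(end) | start_chr != as.character(start) |
                 end_chr != as.character(end))
  if (length(bad) > 0) {
    abort(sprintf("non-integer coordinates in BED at line %d", keep[bad[1]]),
          class = "repcycle_data_error", line = keep[bad[1]])
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("start >= end in BED at line %d", keep[bad[1]]),
          class = "repcycle_data_error", line = keep[bad[1]])
  }
  if (any(start < 0)) {
    abort(sprintf("negative start coordinate in BED at line %d", which(start < 0)[1]),
          class = "repcycle_data_error")
  }
  gene_id <- if (ncol_min >= 4) col(4) else paste0("gene_", seq_along(chrom))
  if (ncol_min >= 6) {
    strand <- col(6)
    if (!all(strand %in% c("+", "-"))) {
      abort(sprintf("invalid strand value at line %d (must be '+' or '-')",
                    which(!strand %in% c("+", "-"))[1]),
            class = "repcycle_data_error")
    }
  } else {
    warn("BED input has no strand column; assuming '+' for all genes")
    strand <- rep("+", length(chrom))
  }
  if (anyDuplicated(gene_id)) {
    abort(sprintf("duplicated gene id: %s", gene_id[duplicated(gene_id)][1]),
          class = "repcycle_data_error")
  }
  tibble(gene_id = gene_id, chrom = chrom, start = start, end = end,
         strand = strand)
}

#' Write genes as BED6
#'
#' @param genes Gene table as returned by [read_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  assert_columns(genes, c("gene_id", "chrom", "start", "end", "strand"), "gene table")
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom, genes$start,
                   genes$end, genes$gene_id, genes$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read an ORI table, keeping only the requested confidence statuses
#'
#' The input is a headered TSV with columns `chrom`, `start`, `end`, `ori_id`,
#' `status` and optionally `firing_time` (synthetic truth only). Rows whose
#' status is not in `statuses` are dropped; the number dropped is reported.
#' Status values outside the known set (confirmed, likely, dubious) are an
#' error.
#'
#' @param path Path to the TSV.
#' @param statuses Character vector of statuses to retain. The default keeps
#'   `confirmed` and `likely` origins only.
#' @return A tibble with columns `ori_id`, `chrom`, `start`, `end`, `status`
#'   (+ `firing_time` when present).
#' @export
read_oris <- function(path, statuses = c("confirmed", "likely")) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                        progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0) {
    warn("empty ORI file; returning an empty ORI table")
    return(tibble(ori_id = character(), chrom = character(), start = integer(),
                  end = integer(), status = character()))
  }
  assert_columns(df, c("chrom", "start", "end", "ori_id", "status"), "ORI table")
  unknown <- setdiff(unique(df$status), ORI_STATUSES)
  if (length(unknown) > 0) {
    abort(sprintf("unknown ORI status value(s): %s", paste(unknown, collapse = ", ")),
          class = "repcycle_data_error")
  }
  if (any(df$start >= df$end)) {
    abort("ORI intervals must satisfy start < end", class = "repcycle_data_error")
  }
  kept <- df[df$status %in% statuses, , drop = FALSE]
  n_drop <- nrow(df) - nrow(kept)
  if (n_drop > 0) {
    inform(sprintf("read_oris: dropped %d of %d origins outside statuses {%s}",
                   n_drop, nrow(df), paste(statuses, collapse = ", ")))
  }
  cols <- c("ori_id", "chrom", "start", "end", "status",
            intersect("firing_time", names(kept)))
  as_tibble(kept[, cols])
}

#' Write an ORI table
#' @param oris ORI table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oris <- function(oris, path) {
  assert_columns(oris, c("ori_id", "chrom", "start", "end", "status"), "ORI table")
  cols <- c("chrom", "start", "end", "ori_id", "status",
            intersect("firing_time", names(oris)))
  write_table(oris[, cols], path)
}

#' Build a replication-timing profile from a position/value table
#'
#' Sorts probes within chromosome, collapses duplicate positions to their mean
#' value (with a warning), and attaches the S-phase bounds used downstream by
#' [classify_early_late()] and for default peak-calling prominence.
#'
#' @param df Data frame with columns `chrom`, `position`, `trep`.
#' @param s_start,s_end Scalars bounding S phase on the same scale as `trep`
#'   (minutes for yeast-style data).
#' @return A tibble of class `trep_profile` sorted by chromosome and position,
#'   with attributes `s_start` and `s_end`.
#' @export
trep_profile <- function(df, s_start, s_end) {
  if (!is.numeric(s_start) || !is.numeric(s_end) || s_start >= s_end) {
    stop_field("s_start/s_end", "S-phase bounds must satisfy s_start < s_end")
  }
  assert_columns(df, c("chrom", "position", "trep"), "T_rep profile")
  if (any(!is.finite(df$trep))) {
    abort("T_rep values must be finite", class = "repcycle_data_error")
  }
  dup <- duplicated(df[, c("chrom", "position")])
  if (any(dup)) {
    warn(sprintf("collapsing %d duplicate probe position(s) to their mean", sum(dup)))
    df <- df %>%
      group_by(.data$chrom, .data$position) %>%
      summarise(trep = mean(.data$trep), .groups = "drop")
  }
  out <- as_tibble(df[, c("chrom", "position", "trep")]) %>%
    arrange(.data$chrom, .data$position)
  attr(out, "s_start") <- s_start
  attr(out, "s_end") <- s_end
  class(out) <- c("trep_profile", class(out))
  out
}

#' Read a bedGraph-like replication-timing profile
#'
#' Accepts either three columns (`chrom`, `position`, `trep`) or four
#' bedGraph columns (`chrom`, `start`, `end`, `trep`), in which case the
#' interval midpoint is used as the probe position. No header. Duplicate
#' positions are collapsed to their mean with a warning.
#'
#' @inheritParams trep_profile
#' @param path Path to the TSV.
#' @return A `trep_profile` tibble; see [trep_profile()].
#' @export
read_trep_profile <- function(path, s_start, s_end) {
  raw <- readLines(path)
  keep <- which(nzchar(raw))
  lines <- raw[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- unique(lengths(fields))
  if (length(nc) != 1 || !nc %in% c(3, 4)) {
    abort("T_rep profile must have 3 (chrom, position, trep) or 4 (chrom, start, end, trep) columns",
          class = "repcycle_data_error")
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  num <- function(i) suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), i)))
  if (nc == 3) {
    position <- num(2)
    trep <- num(3)
  } else {
    position <- interval_midpoint(num(2), num(3))
    trep <- num(4)
  }
  bad <- which(is.na(trep) | is.na(position))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric value in T_rep profile at line %d", keep[bad[1]]),
          class = "repcycle_data_error", line = keep[bad[1]])
  }
  trep_profile(tibble(chrom = chrom, position = position, trep = trep),
               s_start = s_start, s_end = s_end)
}

#' Write a replication-timing profile as 3-column bedGraph-like TSV
#' @param profile A `trep_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trep_profile <- function(profile, path) {
  assert_columns(profile, c("chrom", "position", "trep"), "T_rep profile")
  lines <- paste(profile$chrom, fmt_num(profile$position), fmt_num(profile$trep),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a cell-cycle expression time course
#'
#' The file is a gene x timepoint matrix with a two-row header: the first row
#' holds the sampling times (minutes since release from synchronization), the
#' second the cell-cycle phase label of each timepoint. Values are log2
#' expression ratios relative to asynchronous cells; missing cells are "NA".
#' The result is returned in long (tidy) form.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene_id`, `time`, `phase`, `value`, one row
#'   per gene and timepoint.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) {
    abort("expression file needs a 2-row header plus at least one gene row",
          class = "repcycle_data_error")
  }
  hdr1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  hdr2 <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  times <- suppressWarnings(as.numeric(hdr1[-1]))
  phases <- hdr2[-1]
  if (any(is.na(times))) {
    abort("first header row must contain numeric timepoint minutes",
          class = "repcycle_data_error")
  }
  if (length(times) < 3) {
    abort("an expression time course needs at least 3 timepoints",
          class = "repcycle_data_error")
  }
  if (any(diff(times) <= 0)) {
    abort("timepoint minutes must be strictly increasing",
          class = "repcycle_data_error")
  }
  if (length(phases) != length(times)) {
    abort("phase header row length does not match the timepoint row",
          class = "repcycle_data_error")
  }
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  if (any(lengths(body) != length(times) + 1)) {
    abort(sprintf("ragged expression row at line %d",
                  which(lengths(body) != length(times) + 1)[1] + 2),
          class = "repcycle_data_error")
  }
  gene_id <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(gene_id)) {
    abort(sprintf("duplicated gene id in expression table: %s",
                  gene_id[duplicated(gene_id)][1]),
          class = "repcycle_data_error")
  }
  vals <- do.call(rbind, lapply(body, function(f) {
    suppressWarnings(as.numeric(f[-1]))
  }))
  n_genes <- length(gene_id)
  tibble(
    gene_id = rep(gene_id, each = length(times)),
    time = rep(times, times = n_genes),
    phase = rep(phases, times = n_genes),
    value = as.vector(t(vals))
  )
}

#' Write a cell-cycle expression time course
#'
#' Inverse of [read_expression()]: writes the two-row header (times, phases)
#' followed by one row per gene.
#'
#' @param expr Long-form expression tibble (`gene_id`, `time`, `phase`, `value`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  assert_columns(expr, c("gene_id", "time", "phase", "value"), "expression table")
  tp <- expression_timepoints(expr)
  genes <- unique(expr$gene_id)
  wide <- tidyr::pivot_wider(expr[, c("gene_id", "time", "value")],
                             names_from = "time", values_from = "value")
  wide <- wide[match(genes, wide$gene_id), ]
  hdr1 <- paste(c("gene_id", fmt_num(tp$time)), collapse = "\t")
  hdr2 <- paste(c("phase", tp$phase), collapse = "\t")
  body <- vapply(seq_len(nrow(wide)), function(i) {
    paste(c(wide$gene_id[i], fmt_num(as.numeric(unlist(wide[i, -1])))), collapse = "\t")
  }, character(1))
  writeLines(c(hdr1, hdr2, body), path)
  invisible(path)
}

#' Timepoint annotation of an expression time course
#'
#' @param expr Long-form expression tibble.
#' @return A tibble with one row per timepoint (`time`, `phase`), in time order.
#' @export
expression_timepoints <- function(expr) {
  assert_columns(expr, c("time", "phase"), "expression table")
  distinct(expr[, c("time", "phase")]) %>% arrange(.data$time)
}

#' Read an asynchronous expression table
#'
#' Headered TSV with columns `gene_id`, `level` (non-negative expression
#' scalar) and optionally `per_copy_normalized` (logical; defaults to FALSE).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene_id`, `level`, `per_copy_normalized`.
#' @export
read_async <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  assert_columns(df, c("gene_id", "level"), "asynchronous expression table")
  if (anyDuplicated(df$gene_id)) {
    abort("duplicated gene id in asynchronous expression table",
          class = "repcycle_data_error")
  }
  if (any(!is.finite(df$level)) || any(df$level < 0)) {
    abort("asynchronous levels must be finite and >= 0",
          class = "repcycle_data_error")
  }
  if (!"per_copy_normalized" %in% names(df)) {
    df$per_copy_normalized <- FALSE
  }
  as_tibble(df[, c("gene_id", "level", "per_copy_normalized")])
}

#' Write an asynchronous expression table
#' @param async Asynchronous expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_async <- function(async, path) {
  assert_columns(async, c("gene_id", "level", "per_copy_normalized"),
                 "asynchronous expression table")
  write_table(async, path)
}

#' Write any result table as TSV
#'
#' Numeric columns are formatted with up to 10 significant digits so that a
#' write/read/write cycle is byte-identical; missing values are written "NA".
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  cols <- lapply(x, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  header <- paste(names(x), collapse = "\t")
  body <- do.call(paste, c(cols, sep = "\t"))
  body[is.na(body)] <- "NA"
  writeLines(c(header, body), path)
  invisible(path)
}
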