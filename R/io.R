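# Landmark file IO.  Two dialects:
#  * TPS: "LM3=<p>" header per specimen block, p whitespace-separated
#    coordinate rows, then "ID=<specimen_id>" (replicates > 0 encode as
#    "ID=<id>:rep<k>").  Missing landmarks are the 9999 9999 9999 sentinel.
#  * long CSV: specimen_id,replicate,landmark,x,y,z with blank x,y,z for a
#    missing landmark.  `landmark` may be a 1-based index or a template name.
# Metadata (specimen_id,year,period,sex) lives in a separate CSV joined by
# specimen_id at read time, mirroring museum-catalog workflows.

MISSING_SENTINEL <- 9999

#' Read landmark configurations
#'
#' @param path landmark file.
#' @param format `"tps"` or `"csv"`; default guessed from the extension.
#' @param template the [landmark_template()] the file must conform to.
#' @param metadata optional path to a metadata CSV
#'   (`specimen_id,year,period,sex`) joined by `specimen_id`.
#' @return a [shape_dataset()].
#' @export
read_landmarks <- function(path, format = c("auto", "tps", "csv"), template,
                           metadata = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  if (!file.exists(path)) stop("no such file: ", path)
  p <- length(template$landmark_names)
  parsed <- if (format == "tps") read_tps_blocks(path, p) else read_long_csv(path, template)
  meta <- data.frame(specimen_id = parsed$ids, replicate = parsed$reps,
                     stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    md <- utils::read.csv(metadata, stringsAsFactors = FALSE)
    if (!"specimen_id" %in% names(md)) stop("metadata CSV needs a specimen_id column")
    md <- md[, intersect(c("specimen_id", "year", "period", "sex"), names(md)),
             drop = FALSE]
    meta <- merge(meta, md, by = "specimen_id", all.x = TRUE, sort = FALSE)
    # merge() reorders; restore file order
    meta <- meta[match(paste(parsed$ids, parsed$reps),
                       paste(meta$specimen_id, meta$replicate)), ]
  }
  shape_dataset(template, parsed$coords, meta, parsed$missing)
}

read_tps_blocks <- function(path, p) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3?=", lines)
  n <- length(starts)
  coords <- array(NA_real_, c(n, p, 3))
  missing <- matrix(FALSE, n, p)
  ids <- character(n); reps <- integer(n)
  for (b in seq_len(n)) {
    i <- starts[b]
    declared <- as.integer(sub("^LM3?=", "", lines[i]))
    if (declared != p)
      stop(sprintf("TPS block %d declares %d landmarks; template has %d",
                   b, declared, p))
    block <- lines[(i + 1):(i + declared)]
    for (j in seq_len(declared)) {
      v <- suppressWarnings(as.numeric(strsplit(block[j], "[ \t,]+")[[1]]))
      if (length(v) != 3 || anyNA(v))
        stop(sprintf("TPS block %d (starting line %d): bad coordinate row %d",
                     b, i, j))
      if (all(v == MISSING_SENTINEL)) missing[b, j] <- TRUE else coords[b, j, ] <- v
    }
    tail_lines <- lines[seq(i + declared + 1,
                            min(length(lines), if (b < n) starts[b + 1] - 1 else length(lines)))]
    idl <- grep("^ID=", tail_lines, value = TRUE)
    id <- if (length(idl)) sub("^ID=", "", idl[1]) else sprintf("spec%d", b)
    if (grepl(":rep[0-9]+$", id)) {
      reps[b] <- as.integer(sub(".*:rep", "", id))
      id <- sub(":rep[0-9]+$", "", id)
    }
    ids[b] <- id
  }
  list(coords = coords, missing = missing, ids = ids, reps = reps)
}

read_long_csv <- function(path, template) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(x = "character", y = "character",
                                       z = "character"))
  need <- c("specimen_id", "replicate", "landmark", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("long CSV needs columns: ", paste(need, collapse = ","))
  p <- length(template$landmark_names)
  lm_idx <- suppressWarnings(as.integer(df$landmark))
  named <- is.na(lm_idx)
  lm_idx[named] <- match(df$landmark[named], template$landmark_names)
  if (anyNA(lm_idx) || any(lm_idx < 1 | lm_idx > p))
    stop("unknown landmark label in CSV (specimen ",
         df$specimen_id[which(is.na(lm_idx) | lm_idx < 1 | lm_idx > p)[1]], ")")
  key <- paste(df$specimen_id, df$replicate)
  ukey <- unique(key)
  n <- length(ukey)
  counts <- table(key)
  if (any(counts != p))
    stop("specimen ", names(counts)[which(counts != p)[1]],
         " has ", counts[which(counts != p)[1]], " landmark rows; template has ", p)
  coords <- array(NA_real_, c(n, p, 3))
  missing <- matrix(FALSE, n, p)
  row_grp <- match(key, ukey)
  blank <- !nzchar(trimws(df$x)) & !nzchar(trimws(df$y)) & !nzchar(trimws(df$z))
  xyz <- cbind(suppressWarnings(as.numeric(df$x)),
               suppressWarnings(as.numeric(df$y)),
               suppressWarnings(as.numeric(df$z)))
  for (r in seq_len(nrow(df))) {
    if (blank[r]) missing[row_grp[r], lm_idx[r]] <- TRUE
    else coords[row_grp[r], lm_idx[r], ] <- xyz[r, ]
  }
  first <- match(ukey, key)
  list(coords = coords, missing = missing,
       ids = df$specimen_id[first], reps = as.integer(df$replicate[first]))
}

#' Write landmark configurations
#'
#' Lossless round-trip partner of [read_landmarks()] at 6-decimal precision;
#' missing landmarks are emitted as each format's sentinel (TPS: all-9999
#' row; CSV: blank coordinate fields).
#'
#' @param ds a [shape_dataset()].
#' @param path output file.
#' @param format `"tps"` or `"csv"`.
#' @param digits coordinate precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(ds, path, format = c("tps", "csv"), digits = 6) {
  format <- match.arg(format)
  n <- dim(ds$coords)[1]; p <- dim(ds$coords)[2]
  fmt <- paste0("%.", digits, "f")
  if (format == "tps") {
    out <- character(0)
    for (i in seq_len(n)) {
      rows <- vapply(seq_len(p), function(j) {
        if (ds$missing[i, j]) paste(rep(MISSING_SENTINEL, 3), collapse = " ")
        else paste(sprintf(fmt, ds$coords[i, j, ]), collapse = " ")
      }, character(1))
      id <- ds$meta$specimen_id[i]
      if (ds$meta$replicate[i] > 0) id <- sprintf("%s:rep%d", id, ds$meta$replicate[i])
      out <- c(out, sprintf("LM3=%d", p), rows, sprintf("ID=%s", id), "")
    }
    writeLines(out, path)
  } else {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      xyz <- matrix(sprintf(fmt, ds$coords[i, , ]), p, 3)
      xyz[ds$missing[i, ], ] <- ""
      rows[[i]] <- data.frame(specimen_id = ds$meta$specimen_id[i],
                              replicate = ds$meta$replicate[i],
                              landmark = seq_len(p),
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              stringsAsFactors = FALSE)
    }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write the metadata companion CSV
#' @param ds a [shape_dataset()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(ds, path) {
  md <- unique(ds$meta[, c("specimen_id", "year", "period", "sex")])
  utils::write.csv(md, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
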