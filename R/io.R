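# Readers and writers for the plain-text landmark dialects the pipeline uses:
# TPS files with LM3 records, a long-format CSV, symmetry schemes as YAML or
# CSV tables, and the specimen covariate table.

#' Read 3D landmarks from a TPS file
#'
#' Parses `LM3=` records. `ID=` lines name specimens (falling back to record
#' order), `SCALE=` lines rescale the coordinates of their record, and
#' `IMAGE=`/comment lines are ignored. All records must contain the same
#' number of landmarks.
#'
#' @param path Path to a TPS file.
#' @return An `L x 3 x N` array with specimen identifiers as the third
#'   `dimnames`.
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) stop("no LM3 records found in ", path, call. = FALSE)
  configs <- list()
  ids <- character()
  for (r in seq_along(starts)) {
    from <- starts[r]
    to <- if (r < length(starts)) starts[r + 1L] - 1L else length(lines)
    nlm <- as.integer(sub("^LM3=", "", lines[from], ignore.case = TRUE))
    block <- lines[(from + 1L):to]
    coord_lines <- block[seq_len(nlm)]
    coords <- do.call(rbind, lapply(strsplit(coord_lines, "[ \t]+"), function(p) {
      v <- suppressWarnings(as.numeric(p))
      if (length(v) != 3L || anyNA(v)) {
        stop("malformed coordinate line in TPS record ", r, call. = FALSE)
      }
      v
    }))
    rest <- block[-seq_len(nlm)]
    id <- sub("^ID=", "", grep("^ID=", rest, value = TRUE, ignore.case = TRUE)[1])
    scale <- suppressWarnings(as.numeric(
      sub("^SCALE=", "", grep("^SCALE=", rest, value = TRUE, ignore.case = TRUE)[1])))
    if (is.finite(scale)) coords <- coords * scale
    ids[r] <- if (is.na(id)) sprintf("spec_%03d", r) else id
    configs[[r]] <- coords
  }
  L <- unique(vapply(configs, nrow, integer(1)))
  if (length(L) != 1L) {
    stop("TPS records disagree on landmark count: ", paste(L, collapse = ", "),
         call. = FALSE)
  }
  arr <- array(unlist(configs), dim = c(L, 3L, length(configs)))
  dimnames(arr) <- list(NULL, c("x", "y", "z"), ids)
  arr
}

#' Write 3D landmarks to a TPS file
#'
#' @param configs An `L x 3 x N` array (specimen ids in `dimnames`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  arr <- as_array3d(configs)
  ids <- dimnames(arr)[[3]] %||% sprintf("spec_%03d", seq_len(dim(arr)[3]))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dim(arr)[3])) {
    writeLines(sprintf("LM3=%d", dim(arr)[1]), con)
    writeLines(apply(arr[, , i], 1L, function(p) paste(format(p, digits = 15, trim = TRUE,
                                                              scientific = FALSE),
                                                       collapse = " ")), con)
    writeLines(sprintf("ID=%s", ids[i]), con)
  }
  invisible(path)
}

#' Read landmarks from long-format CSV
#'
#' Expects columns `specimen_id`, `side`, `landmark`, `x`, `y`, `z`, one row
#' per landmark. `side` is `"whole"` for object-symmetric structures, or
#' `"left"`/`"right"` for matching designs (both sides required for every
#' specimen).
#'
#' @param path Path to a CSV file.
#' @return For `side == "whole"` data, an `L x 3 x N` array; for left/right
#'   data, a list with `left` and `right` arrays sharing specimen order.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "side", "landmark", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  build <- function(sub) {
    ids <- unique(sub$specimen_id)
    L <- max(sub$landmark)
    arr <- array(NA_real_, dim = c(L, 3L, length(ids)),
                 dimnames = list(NULL, c("x", "y", "z"), ids))
    for (i in seq_along(ids)) {
      rows <- sub[sub$specimen_id == ids[i], ]
      rows <- rows[order(rows$landmark), ]
      if (nrow(rows) != L || !identical(rows$landmark, 1:L)) {
        stop("specimen ", ids[i], " does not have landmarks 1..", L, call. = FALSE)
      }
      arr[, , i] <- as.matrix(rows[, c("x", "y", "z")])
    }
    arr
  }
  sides <- unique(df$side)
  if (identical(sides, "whole")) return(build(df))
  if (!setequal(sides, c("left", "right"))) {
    stop("side must be 'whole' or both of 'left'/'right'; found: ",
         paste(sides, collapse = ", "), call. = FALSE)
  }
  left <- build(df[df$side == "left", ])
  right <- build(df[df$side == "right", ])
  if (!setequal(dimnames(left)[[3]], dimnames(right)[[3]])) {
    missing <- setdiff(union(dimnames(left)[[3]], dimnames(right)[[3]]),
                       intersect(dimnames(left)[[3]], dimnames(right)[[3]]))
    stop("specimens missing one side: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  right <- right[, , dimnames(left)[[3]], drop = FALSE]
  list(left = left, right = right)
}

#' Write landmarks to long-format CSV
#'
#' @param configs An `L x 3 x N` array, or `list(left = , right = )` of such
#'   arrays for matching designs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(configs, path) {
  one <- function(arr, side) {
    arr <- as_array3d(arr)
    ids <- dimnames(arr)[[3]] %||% sprintf("spec_%03d", seq_len(dim(arr)[3]))
    L <- dim(arr)[1]
    do.call(rbind, lapply(seq_along(ids), function(i) {
      data.frame(specimen_id = ids[i], side = side, landmark = seq_len(L),
                 x = arr[, 1L, i], y = arr[, 2L, i], z = arr[, 3L, i])
    }))
  }
  df <- if (is.list(configs) && !is.null(configs$left)) {
    rbind(one(configs$left, "left"), one(configs$right, "right"))
  } else {
    one(configs, "whole")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a symmetry scheme from YAML or CSV
#'
#' YAML files carry fields `mode`, `axis`, `pairs` (list of `[left, right]`
#' index pairs), `midline` (index list) and optionally `n_landmarks`.
#' CSV files carry columns `type` (`"pair"` or `"midline"`), `left`, `right`
#' (`right` empty on midline rows) plus an optional `mode` column (first value
#' used; default `"object"`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.csv` file.
#' @return A [symmetry_scheme()].
#' @export
read_symmetry_scheme <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    return(symmetry_scheme(mode = y$mode %||% "object",
                           pairs = y$pairs,
                           midline = unlist(y$midline) %||% integer(),
                           n_landmarks = y$n_landmarks,
                           axis = y$axis %||% 1L))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mode <- if ("mode" %in% names(df)) df$mode[1] else "object"
  pr <- df[df$type == "pair", c("left", "right")]
  ml <- df$left[df$type == "midline"]
  symmetry_scheme(mode = mode, pairs = as.matrix(pr), midline = as.integer(ml))
}

#' Write a symmetry scheme to YAML
#'
#' @param scheme A [symmetry_scheme()].
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_symmetry_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "symmetry_scheme"))
  yaml::write_yaml(list(
    mode = scheme$mode,
    axis = scheme$axis,
    n_landmarks = scheme$n_landmarks,
    pairs = lapply(seq_len(nrow(scheme$pairs)), function(i) as.integer(scheme$pairs[i, ])),
    midline = as.integer(scheme$midline)
  ), path)
  invisible(path)
}

#' Read a specimen covariate table
#'
#' Requires columns `specimen_id` and `pct_dom` (percentage of admixed
#' alleles, 0-100); `family_id`, `sex` and `age_weeks` are carried through
#' when present.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame`.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("specimen_id", "pct_dom") %in% names(df))) {
    stop("covariate table must have columns specimen_id and pct_dom", call. = FALSE)
  }
  if (any(!is.finite(df$pct_dom)) || any(df$pct_dom < 0 | df$pct_dom > 100)) {
    stop("pct_dom must lie in [0, 100]", call. = FALSE)
  }
  df
}
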