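#' Read a point cloud from disk
#'
#' CSV/TSV/XYZ are delimited text, one point per row, arbitrary dimension
#' (XYZ fixed at 3 columns); lines starting with \code{#} and a single
#' non-numeric header row are tolerated.  PLY is the ASCII variant with
#' x/y/z vertex properties.  A column named \code{weight} (or announced in a
#' \code{# weights} comment) is read back as point weights.
#'
#' @param path file path.
#' @param format one of \code{"csv"}, \code{"tsv"}, \code{"xyz"},
#'   \code{"ply"}; default guessed from the extension.
#' @return a \code{\link{point_cloud}}.
#' @export
read_point_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("csv", "tsv", "xyz", "ply"))
  if (format == "ply") return(read_ply(path))
  sep <- switch(format, csv = ",", tsv = "\t", xyz = "")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  if (!length(body)) stop("empty point-cloud file: ", path)
  split_row <- function(s) {
    if (sep == "") strsplit(trimws(s), "\\s+")[[1L]]
    else strsplit(s, sep, fixed = TRUE)[[1L]]
  }
  first <- split_row(body[1L])
  header <- suppressWarnings(any(is.na(as.numeric(first))))
  cols <- if (header) first else NULL
  if (header) body <- body[-1L]
  if (!length(body)) stop("no data rows in: ", path)
  rows <- lapply(body, split_row)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("ragged rows in %s (first at line %d)", path,
                 which(keep)[if (header) 2L else 1L] +
                   which(ncols != ncols[1L])[1L] - 1L))
  M <- suppressWarnings(matrix(as.numeric(unlist(rows)),
                               nrow = length(rows), byrow = TRUE))
  if (anyNA(M)) stop("non-numeric cell in: ", path)
  if (format == "xyz" && ncol(M) < 3) stop("xyz files need 3 columns")
  wcol <- if (!is.null(cols)) which(tolower(cols) == "weight") else integer(0)
  if (length(wcol)) {
    point_cloud(M[, -wcol, drop = FALSE], weights = M[, wcol[1L]])
  } else {
    point_cloud(M)
  }
}

#' Write a point cloud to disk
#'
#' Deterministic text output: fixed \code{\%.12g} precision, \code{\\n}
#' newlines, fixed column order; writing the same cloud twice yields
#' byte-identical files.  When the cloud has weights they are written as an
#' extra \code{weight} column announced in the header.
#'
#' @param cloud a \code{\link{point_cloud}}.
#' @param path destination path.
#' @param format as in \code{\link{read_point_cloud}}.
#' @return invisibly, the path.
#' @export
write_point_cloud <- function(cloud, path, format = NULL) {
  cloud <- as_point_cloud(cloud)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("csv", "tsv", "xyz", "ply"))
  if (format == "ply") return(write_ply(cloud, path))
  sep <- switch(format, csv = ",", tsv = "\t", xyz = " ")
  M <- cloud$points
  hdr <- paste0(c(paste0("x", seq_len(cloud$dim)),
                  if (!is.null(cloud$weights)) "weight"), collapse = sep)
  if (!is.null(cloud$weights)) M <- cbind(M, cloud$weights)
  body <- apply(M, 1L, function(r)
    paste(sprintf("%.12g", r), collapse = sep))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

# Minimal ASCII PLY reader: vertex element with x, y, z properties.
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1L]) != "ply")
    stop("not a PLY file: ", path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header not terminated in: ", path)
  header <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format\\s+ascii", header)))
    stop("only ASCII PLY is supported")
  vline <- grep("^element\\s+vertex\\s+\\d+", header, value = TRUE)
  if (!length(vline)) stop("PLY file has no vertex element")
  nv <- as.integer(sub("^element\\s+vertex\\s+(\\d+).*", "\\1", vline[1L]))
  # property names of the vertex element, in order
  vstart <- grep("^element\\s+vertex", header)[1L]
  after <- header[(vstart + 1L):length(header)]
  stopv <- grep("^(element|end_header)", after)[1L]
  props <- sub("^property\\s+\\S+\\s+(\\S+)$", "\\1",
               grep("^property", after[seq_len(stopv - 1L)], value = TRUE))
  rows <- lines[(end + 1L):(end + nv)]
  M <- matrix(as.numeric(unlist(strsplit(trimws(rows), "\\s+"))),
              nrow = nv, byrow = TRUE)
  xyz <- match(c("x", "y", "z"), props)
  if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z properties")
  point_cloud(M[, xyz, drop = FALSE])
}

write_ply <- function(cloud, path) {
  X <- cloud$points
  if (ncol(X) == 2) X <- cbind(X, 0)
  if (ncol(X) != 3) stop("PLY output supports 2-D (z = 0) or 3-D clouds")
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(X)),
           "property float x", "property float y", "property float z",
           "end_header")
  body <- apply(X, 1L, function(r) paste(sprintf("%.12g", r), collapse = " "))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Serialize a mixture model (or fit) to JSON
#'
#' Round-trips losslessly (17 significant digits).  A \code{wmggmm_fit} is
#' written with its weight priors and fit report; a bare
#' \code{\link{mixture_model}} with the model alone.
#'
#' @param x a \code{mixture_model} or \code{wmggmm_fit}.
#' @param path destination JSON path.
#' @return invisibly, the path.
#' @export
write_mixture_json <- function(x, path) {
  fit <- NULL
  if (inherits(x, "wmggmm_fit")) { fit <- x; x <- x$model }
  if (!inherits(x, "mixture_model")) stop("not a mixture model")
  obj <- list(dim = x$dim,
              pi = x$weights_mix,
              components = lapply(x$components, function(cc)
                list(mean = cc$mean, scatter = cc$scatter,
                     beta = cc$shape, m = cc$scale)))
  if (!is.null(fit)) {
    obj$weight_priors <- list(a0 = fit$wstate$a0, b0 = fit$wstate$b0)
    obj$fit_report <- fit$report
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a mixture model from JSON
#'
#' @param path JSON path written by \code{\link{write_mixture_json}}.
#' @return a \code{\link{mixture_model}} (fit report, if present, attached
#'   as attribute \code{"fit_report"}).
#' @export
read_mixture_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- lapply(seq_along(obj$pi), function(k) {
    ck <- if (is.data.frame(obj$components)) {
      list(mean = obj$components$mean[[k]],
           scatter = obj$components$scatter[[k]],
           beta = obj$components$beta[[k]], m = obj$components$m[[k]])
    } else obj$components[[k]]
    mggd_component(unlist(ck$mean), matrix(unlist(ck$scatter), obj$dim),
                   shape = ck$beta, scale = ck$m)
  })
  out <- mixture_model(obj$pi, comps)
  if (!is.null(obj$fit_report)) attr(out, "fit_report") <- obj$fit_report
  out
}

#' Serialize a rigid transform to JSON (and back)
#'
#' @param tf a \code{\link{rigid_transform}}.
#' @param path JSON path.
#' @param extra optional named list merged into the JSON object (e.g. a KLD
#'   trace and seed).
#' @return invisibly, the path.
#' @export
write_transform_json <- function(tf, path, extra = list()) {
  obj <- c(list(angle = tf$angle, rotation = tf$rotation,
                translation = tf$translation), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(translation = obj$translation,
                  rotation = matrix(unlist(obj$rotation),
                                    length(obj$translation)))
}
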