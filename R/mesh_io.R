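#' Read a triangle mesh from file
#'
#' Supports OFF, OBJ, STL (ASCII and binary) and PLY (ASCII and
#' binary_little_endian). Per-vertex scalar properties in PLY beyond the
#' coordinates are preserved as mesh fields; for other formats a sidecar
#' CSV (`<path>.fields.csv`, columns keyed by 0-based vertex index) is read
#' when present. Faces with more than three sides are fan-triangulated.
#' Orientable input with inconsistently oriented faces is reoriented (a
#' message reports how many faces were flipped); non-manifold input is a
#' topology error naming an offending edge.
#'
#' @param path file path.
#' @param fmt one of "auto", "ply", "obj", "off", "stl".
#' @return a `TriMesh`.
#' @export
read_mesh <- function(path, fmt = c("auto", "ply", "obj", "off", "stl")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "auto") {
    fmt <- switch(tolower(tools::file_ext(path)),
                  ply = "ply", obj = "obj", off = "off", stl = "stl",
                  stop("cannot infer mesh format from extension: ", path))
  }
  raw <- switch(fmt,
                ply = read_ply(path),
                obj = read_obj(path),
                off = read_off(path),
                stl = read_stl(path))
  fields <- raw$fields %||% list()
  sidecar <- paste0(path, ".fields.csv")
  if (!length(fields) && file.exists(sidecar)) {
    tab <- utils::read.csv(sidecar)
    if (!"vertex" %in% names(tab))
      stop("sidecar ", sidecar, " must have a 0-based 'vertex' column")
    ord <- order(tab$vertex)
    fields <- lapply(tab[ord, setdiff(names(tab), "vertex"), drop = FALSE],
                     as.numeric)
  }
  or <- orient_faces(raw$faces, nrow(raw$vertices))
  if (or$n_flipped > 0)
    message("read_mesh: reoriented ", or$n_flipped, " face(s) for consistency")
  trimesh(raw$vertices, or$faces, fields = fields)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# make face orientation globally consistent by BFS flips; errors on
# non-manifold or non-orientable input
orient_faces <- function(faces, n_vert) {
  m <- nrow(faces)
  if (m == 0) return(list(faces = faces, n_flipped = 0L))
  K <- as.double(n_vert) + 1
  dir_keys <- function(f) c(f[1] * K + f[2], f[2] * K + f[3], f[3] * K + f[1])
  und_keys <- function(f) {
    a <- c(f[1], f[2], f[3]); b <- c(f[2], f[3], f[1])
    pmin(a, b) * K + pmax(a, b)
  }
  all_und <- t(apply(faces, 1, und_keys))
  byk <- split(rep(seq_len(m), 3), c(all_und))
  if (any(lengths(byk) > 2)) {
    stop("topology error: non-manifold edge shared by ",
         max(lengths(byk)), " faces")
  }
  nbrs <- vector("list", m)
  for (fs in byk[lengths(byk) == 2]) {
    nbrs[[fs[1]]] <- c(nbrs[[fs[1]]], fs[2])
    nbrs[[fs[2]]] <- c(nbrs[[fs[2]]], fs[1])
  }
  flipped <- rep(FALSE, m)
  visited <- rep(FALSE, m)
  out <- faces
  for (seed in seq_len(m)) {
    if (visited[seed]) next
    queue <- seed
    visited[seed] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      kc <- dir_keys(out[cur, ])
      for (nb in nbrs[[cur]]) {
        kf <- dir_keys(out[nb, ])
        f <- out[nb, ]
        kr <- c(f[2] * K + f[1], f[3] * K + f[2], f[1] * K + f[3])
        consistent <- any(kc %in% kr)     # opposite directions on shared edge
        same_dir <- any(kc %in% kf)
        if (!consistent && !same_dir) next
        if (!visited[nb]) {
          if (same_dir && !consistent) {
            out[nb, ] <- rev(out[nb, ])
            flipped[nb] <- TRUE
          }
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        } else if (same_dir && !consistent) {
          stop("topology error: mesh is not orientable")
        }
      }
    }
  }
  list(faces = out, n_flipped = sum(flipped))
}

read_off <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt) & nzchar(trimws(txt))]
  if (!grepl("OFF", txt[1])) stop("format error: missing OFF header in ", path)
  toks <- scan(text = paste(txt[-1], collapse = "\n"), what = numeric(),
               quiet = TRUE)
  nv <- toks[1]; nf <- toks[2]
  pos <- 4
  verts <- matrix(toks[pos:(pos + 3 * nv - 1)], ncol = 3, byrow = TRUE)
  pos <- pos + 3 * nv
  faces <- list()
  for (i in seq_len(nf)) {
    k <- toks[pos]
    idx <- toks[(pos + 1):(pos + k)] + 1
    pos <- pos + k + 1
    for (j in seq_len(k - 2)) {
      faces[[length(faces) + 1L]] <- c(idx[1], idx[j + 1], idx[j + 2])
    }
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- txt[startsWith(txt, "v ")]
  fl <- txt[startsWith(txt, "f ")]
  if (!length(vl) || !length(fl)) stop("format error: no v/f records in ", path)
  verts <- matrix(scan(text = sub("^v ", "", vl), what = numeric(),
                       quiet = TRUE), ncol = 3, byrow = TRUE)
  faces <- list()
  for (line in fl) {
    toks <- strsplit(trimws(sub("^f ", "", line)), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, "", 1))
    idx <- ifelse(idx < 0, nrow(verts) + 1 + idx, idx)
    for (j in seq_len(length(idx) - 2)) {
      faces[[length(faces) + 1L]] <- c(idx[1], idx[j + 1], idx[j + 2])
    }
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  sz <- file.size(path)
  if (length(ntri) == 1 && !is.na(ntri) && sz == 84 + 50 * ntri) {
    tri <- matrix(0, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tri[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vx <- txt[grepl("^\\s*vertex", txt)]
    if (!length(vx)) stop("format error: not a valid STL: ", path)
    tri <- matrix(scan(text = gsub("\\s*vertex\\s*", "", vx),
                       what = numeric(), quiet = TRUE), ncol = 3, byrow = TRUE)
  }
  # merge coincident vertices
  key <- apply(tri, 1, function(r) paste(sprintf("%.9g", r), collapse = ","))
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is ASCII lines up to end_header
  header <- character()
  repeat {
    line <- readBin(con, "raw", 1)
    buf <- raw()
    while (length(line) && line != as.raw(10)) {
      buf <- c(buf, line)
      line <- readBin(con, "raw", 1)
    }
    s <- trimws(rawToChar(buf))
    header <- c(header, s)
    if (s == "end_header") break
    if (length(header) > 200) stop("format error: PLY header not terminated")
  }
  if (header[1] != "ply") stop("format error: missing 'ply' magic in ", path)
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop("format error: unsupported PLY format: ", fmt_line)
  # parse element/property declarations
  elems <- list()
  cur <- NULL
  for (s in header) {
    t <- strsplit(s, "\\s+")[[1]]
    if (t[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = t[2], count = as.integer(t[3]), props = list())
    } else if (t[1] == "property" && !is.null(cur)) {
      if (t[2] == "list") {
        cur$props[[t[5]]] <- list(type = "list", count_type = t[3],
                                  item_type = t[4])
      } else {
        cur$props[[t[3]]] <- list(type = t[2])
      }
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("format error: PLY missing vertex/face elements")
  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  read_scalar <- function(type, n = 1) {
    if (type %in% c("float", "float32", "double", "float64")) {
      readBin(con, "numeric", n, size = type_size[[type]], endian = "little")
    } else {
      readBin(con, "integer", n, size = type_size[[type]], endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
  }
  if (binary) {
    ve <- elems$vertex
    pn <- names(ve$props)
    vd <- matrix(0, ve$count, length(pn), dimnames = list(NULL, pn))
    for (i in seq_len(ve$count)) {
      for (j in seq_along(pn)) {
        vd[i, j] <- read_scalar(ve$props[[j]]$type)
      }
    }
    fe <- elems$face
    faces <- list()
    for (i in seq_len(fe$count)) {
      for (p in fe$props) {
        if (identical(p$type, "list")) {
          k <- read_scalar(p$count_type)
          idx <- read_scalar(p$item_type, k) + 1
          for (j in seq_len(k - 2)) {
            faces[[length(faces) + 1L]] <- c(idx[1], idx[j + 1], idx[j + 2])
          }
        } else {
          read_scalar(p$type)
        }
      }
    }
    faces <- do.call(rbind, faces)
  } else {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    ve <- elems$vertex
    pn <- names(ve$props)
    vtok <- scan(text = paste(rest[seq_len(ve$count)], collapse = "\n"),
                 what = numeric(), quiet = TRUE)
    vd <- matrix(vtok, ve$count, length(pn), byrow = TRUE,
                 dimnames = list(NULL, pn))
    fl <- rest[ve$count + seq_len(elems$face$count)]
    faces <- list()
    for (line in fl) {
      toks <- as.numeric(strsplit(trimws(line), "\\s+")[[1]])
      k <- toks[1]
      idx <- toks[2:(k + 1)] + 1
      for (j in seq_len(k - 2)) {
        faces[[length(faces) + 1L]] <- c(idx[1], idx[j + 1], idx[j + 2])
      }
    }
    faces <- do.call(rbind, faces)
  }
  extra <- setdiff(colnames(vd), c("x", "y", "z", "nx", "ny", "nz",
                                   "red", "green", "blue", "alpha"))
  fields <- lapply(extra, function(nm) as.numeric(vd[, nm]))
  names(fields) <- extra
  list(vertices = unname(vd[, c("x", "y", "z"), drop = FALSE]),
       faces = faces, fields = fields)
}

#' Write a triangle mesh to file
#'
#' OFF, OBJ and ASCII STL/PLY writers. PLY output stores per-vertex scalar
#' fields as extra float properties; for other formats fields go to a
#' sidecar CSV keyed by 0-based vertex index. `read_mesh(write_mesh(x))`
#' round-trips vertices and faces bit-identically for PLY and OFF.
#'
#' @param mesh a `TriMesh`.
#' @param path output path.
#' @param fmt one of "auto", "ply", "obj", "off", "stl".
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, fmt = c("auto", "ply", "obj", "off", "stl")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- switch(tolower(tools::file_ext(path)),
                  ply = "ply", obj = "obj", off = "off", stl = "stl",
                  stop("cannot infer mesh format from extension: ", path))
  }
  v <- mesh$vertices
  f <- mesh$faces
  num <- function(x) sprintf("%.17g", x)
  lines <- switch(
    fmt,
    off = c("OFF",
            paste(nrow(v), nrow(f), 0),
            paste(num(v[, 1]), num(v[, 2]), num(v[, 3])),
            paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1)),
    obj = c(paste("v", num(v[, 1]), num(v[, 2]), num(v[, 3])),
            paste("f", f[, 1], f[, 2], f[, 3])),
    stl = {
      e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
      e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
      nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                   e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                   e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
      nn <- sqrt(rowSums(nrm^2)); nn[nn == 0] <- 1
      nrm <- nrm / nn
      body <- unlist(lapply(seq_len(nrow(f)), function(i) {
        c(paste("facet normal", num(nrm[i, 1]), num(nrm[i, 2]), num(nrm[i, 3])),
          "  outer loop",
          paste("    vertex", num(v[f[i, 1], 1]), num(v[f[i, 1], 2]), num(v[f[i, 1], 3])),
          paste("    vertex", num(v[f[i, 2], 1]), num(v[f[i, 2], 2]), num(v[f[i, 2], 3])),
          paste("    vertex", num(v[f[i, 3], 1]), num(v[f[i, 3], 2]), num(v[f[i, 3], 3])),
          "  endloop", "endfacet")
      }))
      c("solid femurflow", body, "endsolid femurflow")
    },
    ply = {
      fl <- names(mesh$fields)
      props <- c("property double x", "property double y", "property double z",
                 if (length(fl)) paste("property double", fl))
      vcols <- cbind(v, do.call(cbind, mesh$fields[fl]))
      c("ply", "format ascii 1.0",
        paste("element vertex", nrow(v)), props,
        paste("element face", nrow(f)),
        "property list uchar int vertex_indices",
        "end_header",
        do.call(paste, lapply(seq_len(ncol(vcols)), function(j) num(vcols[, j]))),
        paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1))
    })
  writeLines(lines, path)
  if (fmt != "ply" && length(mesh$fields)) {
    tab <- data.frame(vertex = seq_len(nrow(v)) - 1L, mesh$fields)
    utils::write.csv(tab, paste0(path, ".fields.csv"), row.names = FALSE)
  }
  invisible(path)
}
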