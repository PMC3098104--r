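# Fingerprint data model: clones with typed band multisets, matched under a
# size tolerance. Band types correspond to the dyes / protruding-end enzymes
# of a HICF experiment; sizes are scored band lengths in FPC units.

#' Build a fingerprint database
#'
#' The central container for fingerprint analysis: a set of clones, each with
#' a multiset of typed bands, plus the scoring tolerance. Two bands match only
#' if they have the same type and their sizes differ by at most `tolerance`.
#'
#' @param bands data.frame with columns `clone_id`, `band_type` (integer in
#'   `1..k_types`), `size` (positive integer, FPC units).
#' @param tolerance integer band-matching tolerance `t`.
#' @param k_types number of band types (dyes / enzymes).
#' @param markers optional data.frame with columns `clone_id`, `marker_id`
#'   anchoring genetic markers to clones.
#' @return An object of class `FingerprintDB`.
#' @export
fingerprint_db <- function(bands, tolerance = 12L, k_types = 4L,
                           markers = NULL) {
  bands <- as.data.table(bands)[, .(clone_id = as.character(clone_id),
                                    band_type = as.integer(band_type),
                                    size = as.integer(size))]
  if (nrow(bands) > 0L) {
    if (any(bands$size <= 0L)) stop("band sizes must be positive")
    if (any(bands$band_type < 1L | bands$band_type > k_types))
      stop("band_type outside 1..k_types")
  }
  clone_ids <- unique(bands$clone_id)
  setorder(bands, clone_id, band_type, size)
  clones <- bands[, .(n_bands = .N), by = clone_id]
  if (!is.null(markers)) {
    markers <- as.data.table(markers)[, .(clone_id = as.character(clone_id),
                                          marker_id = as.character(marker_id))]
    markers <- unique(markers)
  } else {
    markers <- data.table(clone_id = character(), marker_id = character())
  }
  db <- structure(list(bands = bands, clones = clones,
                       clone_ids = sort(clone_ids),
                       tolerance = as.integer(tolerance),
                       k_types = as.integer(k_types),
                       markers = markers, abundance = NULL),
                  class = "FingerprintDB")
  db
}

#' @export
print.FingerprintDB <- function(x, ...) {
  cat(sprintf(paste0("FingerprintDB: %d clones, %d bands ",
                     "(%.1f per clone), %d band types, tolerance %d\n"),
              nrow(x$clones), nrow(x$bands), db_n_mean(x), x$k_types,
              x$tolerance))
  if (nrow(x$markers)) cat(sprintf("  %d marker anchors (%d markers)\n",
                                   nrow(x$markers),
                                   length(unique(x$markers$marker_id))))
  if (!is.null(x$abundance))
    cat(sprintf("  band abundances estimated for %d classes\n",
                nrow(x$abundance)))
  invisible(x)
}

#' Number of clones and mean bands per clone
#' @param db a `FingerprintDB`
#' @return `db_n_clones`: integer; `db_n_mean`: numeric mean band count.
#' @export
db_n_clones <- function(db) nrow(db$clones)

#' @rdname db_n_clones
#' @export
db_n_mean <- function(db) if (nrow(db$clones)) mean(db$clones$n_bands) else 0

#' Extract one clone's fingerprint
#' @param db a `FingerprintDB`
#' @param id clone id
#' @return list with `clone_id`, `bands` (data.table `band_type`, `size`,
#'   sorted) and `markers` (character vector), class `Fingerprint`.
#' @export
get_fingerprint <- function(db, id) {
  b <- db$bands[clone_id == id, .(band_type, size)]
  if (nrow(b) == 0L) stop("unknown clone id: ", id)
  structure(list(clone_id = id, bands = b,
                 markers = db$markers[clone_id == id, marker_id]),
            class = "Fingerprint")
}

as_band_table <- function(fp) {
  if (inherits(fp, "Fingerprint")) return(fp$bands)
  as.data.table(fp)[, .(band_type = as.integer(band_type),
                        size = as.integer(size))][order(band_type, size)]
}

#' Shared bands between two fingerprints
#'
#' Greedy one-to-one matching per band type over the two sorted size lists:
#' a two-pointer sweep in which each band participates in at most one match
#' and two bands match iff their types are equal and sizes differ by at most
#' `tolerance`.
#'
#' @param fp1,fp2 `Fingerprint` objects or data.frames with `band_type`,`size`.
#' @param tolerance matching tolerance `t`.
#' @return list with `k` (matched count) and `pairs` (two-column matrix of
#'   matched band row indices into the sorted band tables).
#' @export
shared_bands <- function(fp1, fp2, tolerance) {
  b1 <- as_band_table(fp1); b2 <- as_band_table(fp2)
  res <- cpp_pair_overlap(b1$band_type, b1$size, b2$band_type, b2$size,
                          as.integer(tolerance))
  list(k = res$k, pairs = res$pairs)
}

# Concatenated per-clone band arrays for the C++ all-pairs kernel.
# Returns 0-based clone offsets plus aligned type/size/weight vectors.
band_arrays <- function(db, ids = NULL, weights = FALSE) {
  b <- db$bands
  if (!is.null(ids)) b <- b[clone_id %in% ids]
  setorder(b, clone_id, band_type, size)
  cid <- unique(b$clone_id)
  idx <- b[, .N, by = clone_id]
  starts <- c(0L, cumsum(idx$N))
  w <- if (weights) {
    if (is.null(db$abundance)) stop("band abundances not estimated")
    bw <- assign_band_classes(db)
    key <- paste(b$clone_id, b$band_type, b$size)
    bw_key <- paste(bw$clone_id, bw$band_type, bw$size)
    bw$w[match(key, bw_key)]
  } else numeric(0)
  list(starts = as.integer(starts), types = b$band_type, sizes = b$size,
       weights = w, clone_ids = cid)
}

# Pool the size axis of each band type into classes: sorted sizes start a
# new class when the gap to the previous size exceeds the tolerance OR the
# class would grow wider than +/- t around its first member (2t + 1 values).
# The width bound keeps classes tolerance-sized on dense HICF size axes,
# where gaps larger than t are rare; a class then represents one
# distinguishable band value b with its "within tolerance of b" neighborhood.
band_class_table <- function(db) {
  t <- db$tolerance
  u <- unique(db$bands[, .(band_type, size)])
  setorder(u, band_type, size)
  u[, class_id := {
    cl <- integer(.N); cur <- 1L; anchor <- size[1L]
    for (r in seq_len(.N)) {
      if (r > 1L && (size[r] - size[r - 1L] > t || size[r] - anchor > 2L * t)) {
        cur <- cur + 1L; anchor <- size[r]
      }
      cl[r] <- cur
    }
    cl
  }, by = band_type]
  u[, gcl := cumsum(c(TRUE, diff(class_id) != 0 | diff(band_type) != 0))]
  u[]
}

# Per-band global class assignment plus -ln f weight (needs abundances).
assign_band_classes <- function(db) {
  cl <- band_class_table(db)
  b <- copy(db$bands)
  key <- paste(b$band_type, b$size)
  b[, gcl := cl$gcl[match(key, paste(cl$band_type, cl$size))]]
  if (!is.null(db$abundance))
    b[, w := -log(db$abundance$f[match(gcl, db$abundance$gcl)])]
  b[]
}

#' Estimate band abundances
#'
#' Bands are pooled into classes by clustering the sorted size axis of each
#' type (a new class starts when the gap exceeds the tolerance). For each
#' class `b`, `pi_b = N_b / N` is the proportion of clones carrying a band of
#' the class, and the abundance is the small-f maximum-likelihood
#' approximation `f_b = n_mean^-1 * pi_b / (1 - pi_b)`, capped at 1
#' (`pi_b = 1` uses `N` in place of the odds ratio).
#'
#' @param db a `FingerprintDB`
#' @return the database with an `abundance` table (`gcl` global class id,
#'   `band_type`, `size_lo`, `size_hi`, `n_clones`, `pi_b`, `f`).
#' @export
estimate_abundances <- function(db) {
  stopifnot(db_n_clones(db) >= 1L)
  cl <- band_class_table(db)
  b <- copy(db$bands)
  key <- paste(b$band_type, b$size)
  b[, gcl := cl$gcl[match(key, paste(cl$band_type, cl$size))]]
  N <- db_n_clones(db)
  nm <- db_n_mean(db)
  ab <- b[, .(n_clones = uniqueN(clone_id)), by = gcl]
  rng <- cl[, .(band_type = band_type[1L], size_lo = min(size),
                size_hi = max(size)), by = gcl]
  ab <- rng[ab, on = "gcl"]
  ab[, pi_b := n_clones / N]
  ab[, f := ifelse(pi_b >= 1, N / nm, pi_b / (1 - pi_b) / nm)]
  ab[, f := pmin(f, 1)]
  setorder(ab, gcl)
  db$abundance <- ab[]
  db
}

#' Detect buried clones
#'
#' Clone `c_i` is buried in `c_j` when it has no more bands than `c_j` and at
#' least a fraction `q` of its bands match bands of `c_j`. Mutual burial
#' (equal band counts) is resolved lexicographically: the smaller clone id
#' becomes the host.
#'
#' @param db a `FingerprintDB`
#' @param q burial threshold in (0, 1]; default 0.90.
#' @return data.table with columns `buried`, `host`, `k`, `frac` (one row per
#'   buried clone, keeping the host with the highest matched fraction).
#' @export
find_buried <- function(db, q = 0.90) {
  stopifnot(q > 0, q <= 1)
  if (db_n_clones(db) < 2L)
    return(data.table(buried = character(), host = character(),
                      k = integer(), frac = numeric()))
  arr <- band_arrays(db)
  nb <- setNames(db$clones$n_bands, db$clones$clone_id)
  minn <- min(nb)
  res <- as.data.table(cpp_all_pairs(arr$starts, arr$types, arr$sizes,
                                     numeric(0), db$tolerance,
                                     max(1L, as.integer(ceiling(q * minn)))))
  if (nrow(res) == 0L)
    return(data.table(buried = character(), host = character(),
                      k = integer(), frac = numeric()))
  res[, c1 := arr$clone_ids[i]][, c2 := arr$clone_ids[j]]
  res[, `:=`(n1 = nb[c1], n2 = nb[c2])]
  # orient: buried = fewer bands, lexicographic on ties
  res[, buried := ifelse(n1 < n2 | (n1 == n2 & c1 > c2), c1, c2)]
  res[, host := ifelse(buried == c1, c2, c1)]
  res[, frac := k / pmin(n1, n2)]
  out <- res[frac >= q, .(buried, host, k, frac)]
  setorder(out, buried, -frac, host)
  out[, head(.SD, 1L), by = buried]
}

#' Read an FPC sizes file
#'
#' Each record is a header line `cloneName bandCount` followed by
#' whitespace-separated integer sizes terminated by `-1`. With
#' `offsets = TRUE` the band type is decoded from the size as
#' `1 + floor(size / offset_unit)` and the size is reduced modulo the offset
#' unit (the encoding used to pack typed HICF bands into untyped FPC sizes).
#'
#' @param path sizes file.
#' @param k_types number of band types.
#' @param tolerance band-matching tolerance.
#' @param offsets decode band types from size offsets?
#' @param offset_unit offset per type (default 5000).
#' @param markers optional marker TSV path (`clone_id<TAB>marker_id`).
#' @return a `FingerprintDB`
#' @export
read_sizes <- function(path, k_types = 4L, tolerance = 12L, offsets = TRUE,
                       offset_unit = 5000L, markers = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  recs <- list(); ids <- character()
  i <- 1L
  while (i <= length(toks)) {
    id <- toks[i]
    if (i + 1L > length(toks)) stop("truncated record for clone ", id)
    cnt <- suppressWarnings(as.integer(toks[i + 1L]))
    if (is.na(cnt)) stop("bad band count for clone ", id)
    j <- i + 2L
    sizes <- integer(0)
    while (j <= length(toks) && toks[j] != "-1") {
      v <- suppressWarnings(as.integer(toks[j]))
      if (is.na(v)) stop("bad band size '", toks[j], "' in clone ", id)
      sizes <- c(sizes, v)
      j <- j + 1L
    }
    if (j > length(toks)) stop("record for clone ", id, " not terminated")
    if (length(sizes) != cnt)
      stop("clone ", id, ": declared ", cnt, " bands, found ", length(sizes))
    if (any(sizes <= 0L)) stop("clone ", id, ": non-positive band size")
    if (id %in% ids) stop("duplicate clone id: ", id)
    ids <- c(ids, id)
    recs[[id]] <- sizes
    i <- j + 1L
  }
  if (length(recs) == 0L)
    return(fingerprint_db(data.table(clone_id = character(),
                                     band_type = integer(), size = integer()),
                          tolerance, k_types, read_marker_tsv(markers)))
  bands <- data.table(clone_id = rep(ids, lengths(recs)),
                      size = unlist(recs, use.names = FALSE))
  if (offsets) {
    bands[, band_type := pmin(k_types, 1L + size %/% as.integer(offset_unit))]
    bands[, size := size - (band_type - 1L) * as.integer(offset_unit)]
    if (any(bands$size <= 0L))
      stop("offset decoding produced non-positive size; ",
           "check offsets/offset_unit")
  } else {
    bands[, band_type := 1L]
  }
  fingerprint_db(bands, tolerance, k_types, read_marker_tsv(markers))
}

read_marker_tsv <- function(path) {
  if (is.null(path)) return(NULL)
  m <- fread(path, header = FALSE, col.names = c("clone_id", "marker_id"),
             colClasses = "character")
  m
}

#' Write an FPC sizes file
#' @param db a `FingerprintDB`
#' @param path output file
#' @param offsets re-encode band types as size offsets?
#' @param offset_unit offset per type
#' @export
write_sizes <- function(db, path, offsets = TRUE, offset_unit = 5000L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(db$bands$clone_id)) {
    b <- db$bands[clone_id == id]
    sz <- if (offsets) b$size + (b$band_type - 1L) * as.integer(offset_unit)
          else b$size
    writeLines(paste(id, length(sz)), con)
    writeLines(paste(c(sz, -1L), collapse = " "), con)
  }
  invisible(path)
}

#' Read / write the plain band TSV alternative (`clone_id band_type size`)
#' @param path TSV file
#' @param tolerance,k_types,markers as in [read_sizes()]
#' @export
read_bands_tsv <- function(path, tolerance = 12L, k_types = 4L,
                           markers = NULL) {
  b <- fread(path, col.names = c("clone_id", "band_type", "size"))
  fingerprint_db(b, tolerance, k_types, read_marker_tsv(markers))
}

#' @rdname read_bands_tsv
#' @param db a `FingerprintDB`
#' @export
write_bands_tsv <- function(db, path) {
  fwrite(db$bands[, .(clone_id, band_type, size)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}
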