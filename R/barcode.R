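## Cell/spot barcode assignment from softclips.
##
## Matching works against a reference whitelist: candidate barcodes are
## pulled from an 8-mer index over a positional search region, then ranked
## by infix edit distance. Start positions of confident matches feed back
## into a normal prior that narrows the search region on a second pass.

#' Read a barcode whitelist
#'
#' One barcode per line, plain text or gzip. Trailing gem-group style
#' suffixes (e.g. `"-1"`) are stripped.
#'
#' @param path file path.
#' @return Character vector of barcodes (deduplicated, upper case).
#' @export
read_whitelist <- function(path) {
  bc <- readLines(path)
  bc <- toupper(sub("-[0-9]+$", "", trimws(bc)))
  bc <- bc[nzchar(bc)]
  unique(bc)
}

#' Build a k-mer index over a barcode whitelist
#'
#' Every barcode is registered under each of its `L - k + 1` k-mers, so a
#' softclip region sharing at least one k-mer with a barcode retrieves it
#' as a candidate.
#'
#' @param whitelist character vector of equal-length barcodes (A,C,G,T).
#' @param k k-mer size (default 8).
#' @return List of class `barcode_index` with `k`, `bc_len`, `barcodes`
#'   and the k-mer hash `kmer_map` (environment: k-mer -> integer indices
#'   into `barcodes`).
#' @export
build_kmer_index <- function(whitelist, k = 8L) {
  if (anyDuplicated(whitelist)) {
    warning("duplicate barcodes in whitelist; deduplicated")
    whitelist <- unique(whitelist)
  }
  lens <- unique(nchar(whitelist))
  if (length(lens) != 1L) stop("whitelist barcodes must have uniform length")
  if (lens < k) stop("k (", k, ") exceeds barcode length (", lens, ")")
  env <- new.env(hash = TRUE, parent = emptyenv(), size = length(whitelist) * 4L)
  starts <- seq_len(lens - k + 1L)
  for (i in seq_along(whitelist)) {
    km <- unique(substring(whitelist[i], starts, starts + k - 1L))
    for (m in km) {
      env[[m]] <- c(env[[m]], i)
    }
  }
  structure(list(k = as.integer(k), bc_len = as.integer(lens),
                 barcodes = whitelist, kmer_map = env),
            class = "barcode_index")
}

#' Normal prior over barcode start positions
#'
#' @param mean,sd prior mean and s.d. of the barcode start position
#'   (1-based nt within the retained softclip).
#' @param n_obs number of confident alignments the prior is based on.
#' @param sd_floor lower bound for `sd` (default 1 nt).
#' @return List of class `position_prior`.
#' @export
position_prior <- function(mean, sd, n_obs = 0L, sd_floor = 1) {
  structure(list(mean = mean, sd = max(sd, sd_floor), n_obs = n_obs,
                 sd_floor = sd_floor),
            class = "position_prior")
}

#' Default (first-pass) position prior covering a whole softclip
#' @param softclip_retain retained softclip length (default 55).
#' @return A [position_prior()] with mean at the clip midpoint and s.d. a
#'   quarter of the clip, so the 95% search interval spans the clip.
#' @export
initial_position_prior <- function(softclip_retain = 55L) {
  position_prior(mean = softclip_retain / 2, sd = softclip_retain / 4)
}

#' Match one softclip against the whitelist
#'
#' The search region is the clip substring spanning the prior's 95%
#' interval (mean +/- 1.96 sd), clipped to the sequence and padded by one
#' barcode length so that a barcode starting inside the interval fits.
#' Whitelist barcodes sharing at least one k-mer with the region are
#' candidates; the candidate with the unique minimum infix edit distance
#' wins. Ambiguous minima (two or more candidates) leave the read
#' unassigned, since a wrong barcode corrupts the downstream UMI pool.
#'
#' @param softclip softclip string, adapter->transcript orientation.
#' @param index a [build_kmer_index()].
#' @param prior a [position_prior()].
#' @return List with `barcode` (string or `NA`), `edit_distance`,
#'   `start_pos` (1-based within the clip, `NA` if unassigned) and
#'   `n_candidates`.
#' @export
match_barcode <- function(softclip, index, prior) {
  L <- nchar(softclip)
  miss <- list(barcode = NA_character_, edit_distance = NA_integer_,
               start_pos = NA_integer_, end_pos = NA_integer_,
               n_candidates = 0L)
  if (is.na(softclip) || L < index$k) return(miss)
  z <- 1.96
  lo <- max(1L, floor(prior$mean - z * prior$sd))
  hi <- min(L, ceiling(prior$mean + z * prior$sd) + index$bc_len - 1L)
  if (hi - lo + 1L < index$k) return(miss)
  region <- substr(softclip, lo, hi)
  starts <- seq_len(nchar(region) - index$k + 1L)
  kms <- unique(substring(region, starts, starts + index$k - 1L))
  cand <- unique(unlist(lapply(kms, function(m) index$kmer_map[[m]]),
                        use.names = FALSE))
  if (length(cand) == 0) return(miss)
  res <- lapply(index$barcodes[cand], infix_edit_distance, text = region)
  d <- vapply(res, `[[`, numeric(1), "dist")
  best <- min(d)
  at_min <- which(d == best)
  if (length(at_min) != 1L) {
    return(list(barcode = NA_character_, edit_distance = as.integer(best),
                start_pos = NA_integer_, end_pos = NA_integer_,
                n_candidates = length(at_min)))
  }
  list(barcode = index$barcodes[cand[at_min]],
       edit_distance = as.integer(best),
       start_pos = lo + res[[at_min]]$start,      # infix start is 0-based
       end_pos = lo + res[[at_min]]$end - 1L,     # last matched base, 1-based
       n_candidates = 1L)
}

#' Update the start-position prior from confident matches
#'
#' Replaces the prior mean and s.d. with the empirical mean and s.d. of
#' the start positions of confident matches (edit distance at most
#' `confident_ed`), with the s.d. floored.
#'
#' @param prior a [position_prior()].
#' @param matches data.frame with `edit_distance` and `start_pos` columns.
#' @param confident_ed edit-distance cutoff for "confident" (default 1).
#' @return Updated [position_prior()]; unchanged when no match qualifies.
#' @export
update_position_prior <- function(prior, matches, confident_ed = 1L) {
  ok <- !is.na(matches$edit_distance) &
    matches$edit_distance <= confident_ed & !is.na(matches$start_pos)
  sp <- matches$start_pos[ok]
  if (length(sp) == 0) return(prior)
  s <- if (length(sp) > 1) sd(sp) else 0
  position_prior(mean = mean(sp), sd = s, n_obs = length(sp),
                 sd_floor = prior$sd_floor)
}

#' Default edit-distance cutoff for barcode acceptance
#' @param bc_len barcode length.
#' @return 3 for the common 16 nt barcode, else `ceiling(bc_len / 5)`.
#' @export
default_max_ed <- function(bc_len) {
  if (bc_len == 16L) 3L else as.integer(ceiling(bc_len / 5))
}

#' Flag low-quality barcode matches
#'
#' A match passes when its edit distance is at most `max_ed` (inclusive)
#' and its start position lies within `max_z` prior s.d. of the prior
#' mean.
#'
#' @param matches data.frame with `barcode`, `edit_distance`, `start_pos`.
#' @param prior finalized [position_prior()].
#' @param max_ed inclusive edit-distance cutoff.
#' @param max_z start-position z-score cutoff (default 3).
#' @return The data.frame with a logical `pass` column set.
#' @export
filter_matches <- function(matches, prior, max_ed = 3L, max_z = 3) {
  zdev <- abs(matches$start_pos - prior$mean) / prior$sd
  matches$pass <- !is.na(matches$barcode) &
    matches$edit_distance <= max_ed &
    !is.na(zdev) & zdev <= max_z
  matches
}

#' Assign cell barcodes to a table of reads (two-pass)
#'
#' Pass one matches every softclip under the wide initial prior and
#' collects confident (edit distance <= `confident_ed`) start positions;
#' the prior is then updated once, in a batch, and every read is matched
#' again under the narrowed search region. Batching makes the result
#' independent of read order.
#'
#' @param reads data.frame with `read_id` and `bc_clip` columns
#'   (from [extract_reads()]).
#' @param whitelist character vector of barcodes, or a prebuilt
#'   [build_kmer_index()].
#' @param max_ed inclusive edit-distance cutoff (default
#'   [default_max_ed()] of the barcode length).
#' @param max_z start-position z cutoff (default 3).
#' @param confident_ed cutoff for prior-updating matches (default 1).
#' @param softclip_retain retained clip length used for the initial prior.
#' @return List with `matches` (data.frame: read_id, barcode,
#'   edit_distance, start_pos, pass) and the final `prior`.
#' @export
assign_barcodes <- function(reads, whitelist, max_ed = NULL, max_z = 3,
                            confident_ed = 1L, softclip_retain = 55L) {
  index <- if (inherits(whitelist, "barcode_index")) whitelist
           else build_kmer_index(whitelist)
  if (is.null(max_ed)) max_ed <- default_max_ed(index$bc_len)
  prior0 <- initial_position_prior(softclip_retain)
  pass1 <- match_many(reads, index, prior0)
  prior <- update_position_prior(prior0, pass1, confident_ed)
  pass2 <- if (prior$n_obs > 0) match_many(reads, index, prior) else pass1
  pass2 <- filter_matches(pass2, prior, max_ed = max_ed, max_z = max_z)
  list(matches = pass2, prior = prior)
}

match_many <- function(reads, index, prior) {
  res <- lapply(reads$bc_clip, match_barcode, index = index, prior = prior)
  data.frame(
    read_id = reads$read_id,
    barcode = vapply(res, `[[`, "", "barcode"),
    edit_distance = vapply(res, function(r) as.integer(r$edit_distance),
                           integer(1)),
    start_pos = vapply(res, function(r) as.integer(r$start_pos), integer(1)),
    end_pos = vapply(res, function(r) as.integer(r$end_pos), integer(1)),
    stringsAsFactors = FALSE
  )
}
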