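#' Read a BORIS-style tabular annotation export
#'
#' Reads a delimited event log (comma or tab, auto-detected) and returns a
#' normalized event table. Column names are matched case-insensitively against
#' common BORIS export headers: time (`time`, `time_s`, `start (s)`), subject
#' (`subject`, `actor`), behavior (`behavior`, `behavior code`, `code`), status
#' (`status`, `behavior type`, `event type`) and video id (`video_id`,
#' `observation id`, `media file`, `video`). A missing subject column defaults
#' to `"either"`; a missing video column defaults to a single video.
#'
#' @param path Path to a CSV/TSV event log.
#' @return A data.frame with columns `video_id`, `time_s`, `actor`, `behavior`,
#'   `status` (START/STOP/POINT), sorted by video and time.
#' @export
read_boris <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(candidates, required = TRUE) {
    hit <- match(candidates, tolower(trimws(names(raw))))
    hit <- hit[!is.na(hit)]
    if (!length(hit)) {
      if (required) stop("no column matching any of: ",
                         paste(candidates, collapse = ", "))
      return(NULL)
    }
    raw[[hit[1]]]
  }
  time_s <- as.numeric(pick(c("time", "time_s", "start (s)")))
  behavior <- as.character(pick(c("behavior", "behavior code", "code")))
  status <- toupper(trimws(as.character(pick(c("status", "behavior type",
                                               "event type")))))
  actor <- pick(c("subject", "actor"), required = FALSE)
  actor <- if (is.null(actor)) "either" else tolower(trimws(as.character(actor)))
  video <- pick(c("video_id", "observation id", "media file", "video"),
                required = FALSE)
  video <- if (is.null(video)) "video1" else as.character(video)
  if (anyNA(time_s) || any(time_s < 0)) {
    stop("event times must be finite and non-negative")
  }
  ok <- status %in% c("START", "STOP", "POINT")
  if (!all(ok)) stop("unrecognized status value(s): ",
                     paste(unique(status[!ok]), collapse = ", "))
  out <- data.frame(video_id = video, time_s = time_s, actor = actor,
                    behavior = behavior, status = status,
                    stringsAsFactors = FALSE)
  out[order(out$video_id, out$time_s), , drop = FALSE]
}

#' Pair START/STOP annotation events into behavior episodes
#'
#' Each START is matched, within the same video, behavior and actor, to the
#' next unmatched STOP at or after it (first-in-first-out). POINT events become
#' zero-length episodes. Episodes from different behaviors may overlap in time;
#' each is kept independently. Episode labels are consolidated into leaf
#' categories via [consolidate()].
#'
#' @param events A data.frame with columns `video_id`, `time_s`, `actor`,
#'   `behavior`, `status`, as returned by [read_boris()].
#' @param ethogram Ethogram used for consolidation.
#' @return A data.frame with columns `video_id`, `behavior`, `actor`, `leaf`,
#'   `parent`, `start_s`, `end_s`.
#' @export
pair_events <- function(events, ethogram = default_ethogram()) {
  req <- c("video_id", "time_s", "actor", "behavior", "status")
  if (!all(req %in% names(events))) {
    stop("events must have columns: ", paste(req, collapse = ", "))
  }
  events <- events[order(events$video_id, events$time_s), , drop = FALSE]
  key <- paste(events$video_id, .normalize_code(events$behavior), events$actor,
               sep = "\r")
  out <- vector("list", length(unique(key)))
  ki <- 0L
  for (k in unique(key)) {
    ev <- events[key == k, , drop = FALSE]
    starts <- numeric(0)
    st <- en <- numeric(0)
    for (i in seq_len(nrow(ev))) {
      s <- ev$status[i]
      if (s == "POINT") {
        st <- c(st, ev$time_s[i]); en <- c(en, ev$time_s[i])
      } else if (s == "START") {
        starts <- c(starts, ev$time_s[i])
      } else { # STOP
        if (!length(starts)) {
          stop(sprintf("STOP without matching START: behavior '%s' (%s) at %gs in video '%s'",
                       ev$behavior[i], ev$actor[i], ev$time_s[i], ev$video_id[i]))
        }
        st <- c(st, starts[1]); en <- c(en, ev$time_s[i])
        starts <- starts[-1]
      }
    }
    if (length(starts)) {
      stop(sprintf("unmatched START at end of log: behavior '%s' (%s) at %gs in video '%s'",
                   ev$behavior[1], ev$actor[1], starts[1], ev$video_id[1]))
    }
    if (length(st)) {
      ki <- ki + 1L
      out[[ki]] <- data.frame(video_id = ev$video_id[1],
                              behavior = ev$behavior[1], actor = ev$actor[1],
                              start_s = st, end_s = en,
                              stringsAsFactors = FALSE)
    }
  }
  ep <- do.call(rbind, out[seq_len(ki)])
  if (is.null(ep)) {
    ep <- data.frame(video_id = character(), behavior = character(),
                     actor = character(), start_s = numeric(),
                     end_s = numeric(), stringsAsFactors = FALSE)
  }
  if (any(ep$end_s < ep$start_s)) stop("episode with end before start")
  ep$leaf <- if (nrow(ep)) consolidate(ep$behavior, ep$actor, ethogram) else character()
  ep$parent <- if (nrow(ep)) leaf_parent(ep$leaf) else character()
  ep <- ep[order(ep$video_id, ep$start_s), , drop = FALSE]
  rownames(ep) <- NULL
  ep[, c("video_id", "behavior", "actor", "leaf", "parent", "start_s", "end_s")]
}

#' Expand behavior episodes into temporal samples at a fixed rate
#'
#' Samples are drawn at `start_s + i/fps` for `i = 0, 1, ...` over the
#' half-open interval `[start_s, end_s)`, so adjoining episodes never
#' double-count a boundary instant. Zero-length (point) episodes yield exactly
#' one sample at their timestamp. Overlapping episodes each emit their own
#' samples, so one timestamp may carry several labels.
#'
#' @param episodes Episode data.frame from [pair_events()] (needs `video_id`,
#'   `leaf`, `start_s`, `end_s`).
#' @param fps Sampling rate per second (default 3).
#' @return A data.frame with columns `video_id`, `time_s`, `leaf`, `parent`.
#' @export
episodes_to_samples <- function(episodes, fps = 3) {
  stopifnot(fps > 0)
  n_i <- pmax(1L, as.integer(ceiling((episodes$end_s - episodes$start_s) * fps - 1e-9)))
  idx <- rep(seq_len(nrow(episodes)), n_i)
  offsets <- sequence(n_i) - 1L
  out <- data.frame(video_id = episodes$video_id[idx],
                    time_s = episodes$start_s[idx] + offsets / fps,
                    leaf = episodes$leaf[idx],
                    stringsAsFactors = FALSE)
  out$parent <- leaf_parent(out$leaf)
  out <- out[order(out$video_id, out$time_s, out$leaf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement between two raters over the same items:
#' `(p_o - p_e) / (1 - p_e)`, with observed agreement `p_o` and chance
#' agreement `p_e` from the product of the raters' marginal label frequencies.
#' When both raters are constant and identical (`p_e = 1`), returns 1 by
#' convention with a warning.
#'
#' @param ratings_a,ratings_b Equal-length label vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' cohens_kappa(c("a", "a", "b"), c("a", "a", "b"))  # 1
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating vectors must have equal length")
  }
  lv <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(ratings_a, levels = lv)
  b <- factor(ratings_b, levels = lv)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < .Machine$double.eps) {
    warning("both raters constant and identical; kappa = 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Write a labeled temporal sample table to CSV
#'
#' @param samples Data.frame from [episodes_to_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
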