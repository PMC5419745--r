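# Substitution and indel accounting between ancestral and descendant
# domain sequences, and cumulative normalized change profiles along a
# lineage through evolutionary time.

#' Count substitutions and indel events between two aligned sequences
#'
#' Substitutions are columns where both sequences carry residues that
#' differ; columns containing `X` in either sequence are excluded
#' (masked positions carry no signal). An indel event is a maximal run
#' of consecutive columns gapped in exactly one of the two sequences,
#' counted once regardless of length; `per_column = TRUE` counts gapped
#' columns instead.
#'
#' @param seqA,seqB Aligned residue strings of equal length over the
#'   same column coordinates.
#' @param per_column Count individual indel columns rather than maximal
#'   runs.
#' @return List with `substitutions` and `indel_events` counts.
#' @export
count_changes <- function(seqA, seqB, per_column = FALSE) {
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  if (length(a) != length(b))
    stop("sequences must have equal aligned lengths")
  masked <- a == "X" | b == "X"
  res_a <- a != "-" & !masked
  res_b <- b != "-" & !masked
  subs <- sum(res_a & res_b & a != b)
  one_gap <- xor(a == "-", b == "-") & !masked
  if (per_column) {
    indels <- sum(one_gap)
  } else {
    r <- rle(one_gap)
    indels <- sum(r$values)
  }
  list(substitutions = as.integer(subs), indel_events = as.integer(indels))
}

#' Domain window on master-alignment coordinates
#'
#' @param name Domain name.
#' @param start,end 1-based inclusive alignment column indices.
#' @return A `domain_window` list.
#' @export
domain_window <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1 || end < start) stop("require 1 <= start <= end")
  structure(list(name = name, start = start, end = end),
            class = "domain_window")
}

#' Cumulative normalized change profile along a lineage
#'
#' For each consecutive ancestor/descendant pair on a lineage path,
#' counts substitutions and indel events within the domain window,
#' normalizes by the descendant's non-gap residue count in the window,
#' and accumulates the fractions against node ages.
#'
#' @param sequences Named character vector: one aligned sequence per
#'   lineage node (master-alignment coordinates).
#' @param path Character vector of node names, oldest to youngest.
#' @param ages Numeric vector of node ages (Myr before present,
#'   nonincreasing), same length as `path`. Nodes sharing an age (e.g.
#'   successive whole-genome duplications) may be offset with
#'   `age_offset` for plotting.
#' @param window A `domain_window` (or NULL for the full alignment).
#' @param per_column Passed to [count_changes()].
#' @param age_offset Arbitrary Myr offset applied to break ties among
#'   equal ages (youngest of the tied pair is shifted toward the
#'   present); 0 disables.
#' @return Data frame with one row per step: `from_node`, `to_node`,
#'   `age`, `substitutions`, `indels`, `domain_length`, `normalized`,
#'   `cumulative`.
#' @export
cumulative_profile <- function(sequences, path, ages, window = NULL,
                               per_column = FALSE, age_offset = 0) {
  if (length(path) < 2) stop("lineage path needs at least two nodes")
  if (length(ages) != length(path)) stop("one age per path node")
  if (any(diff(ages) > 0)) stop("node ages must be nonincreasing")
  missing <- setdiff(path, names(sequences))
  if (length(missing))
    stop("missing sequences for nodes: ", paste(missing, collapse = " "))
  if (age_offset > 0) {
    for (i in seq_along(ages)[-1]) {
      if (ages[i] >= ages[i - 1]) ages[i] <- ages[i - 1] - age_offset
    }
  }
  slice <- function(s) {
    if (is.null(window)) s else substr(s, window$start, window$end)
  }
  out <- data.frame()
  cum <- 0
  for (i in seq_along(path)[-1]) {
    sa <- slice(sequences[[path[i - 1]]])
    sb <- slice(sequences[[path[i]]])
    cc <- count_changes(sa, sb, per_column = per_column)
    chars <- strsplit(sb, "")[[1]]
    dlen <- sum(chars != "-" & chars != "X")
    if (dlen == 0) stop("descendant domain has no residues in window")
    norm <- (cc$substitutions + cc$indel_events) / dlen
    cum <- cum + norm
    out <- rbind(out, data.frame(
      from_node = path[i - 1], to_node = path[i], age = ages[i],
      substitutions = cc$substitutions, indels = cc$indel_events,
      domain_length = dlen, normalized = norm, cumulative = cum))
  }
  out
}
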