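#' Build a sliding-window grid
#'
#' Windows of `size` bp advancing by `step` bp (default 40 kb with a 20 kb
#' slide), 0-based half-open. Window starts run `0, step, 2*step, ...` while
#' the start lies inside the chromosome; terminal windows truncated at the
#' chromosome end are kept and flagged.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param size Window size in bp.
#' @param step Slide in bp; must satisfy `0 < step <= size`.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `truncated`, with attributes `size` and `step` identifying the grid.
#' @export
make_windows <- function(chrom_lengths, size = 40000, step = 20000) {
  if (step <= 0 || step > size)
    stop("require 0 < step <= size (step > size would leave gaps)")
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chrom_lengths must be a named vector of positive lengths")
  out <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + size, len)
    data.frame(chrom = ch, start = starts, end = ends,
               truncated = (ends - starts) < size, stringsAsFactors = FALSE)
  }))
  attr(out, "size") <- size
  attr(out, "step") <- step
  out
}
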