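# 3D connected-component labelling on logical arrays.  Written in plain R
# with a stack-based flood fill over precomputed neighbour offsets; lesion
# masks here are a few thousand voxels, far below where compiled code would
# pay off.

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6"  = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3D mask
#'
#' @param mask 3D logical array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
#' @return integer array of the same shape: 0 outside the mask, otherwise a
#'   component id (1, 2, ...). Component ids are ordered by first voxel in
#'   array order.
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  offs <- neighbour_offsets(connectivity)
  # linear-index offsets are only safe away from the array faces; guard by
  # comparing unpacked coordinates of each candidate neighbour
  labels <- array(0L, d)
  idx_all <- which(mask)
  if (!length(idx_all)) return(labels)
  nxt <- 0L
  for (seed in idx_all) {
    if (labels[seed] != 0L) next
    nxt <- nxt + 1L
    stack <- seed
    labels[seed] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cz <- (cur - 1L) %/% (d[1] * d[2])
      rem <- (cur - 1L) %% (d[1] * d[2])
      cy <- rem %/% d[1]
      cx <- rem %% d[1]
      nx <- cx + offs[, 1]; ny <- cy + offs[, 2]; nz <- cz + offs[, 3]
      ok <- nx >= 0 & nx < d[1] & ny >= 0 & ny < d[2] & nz >= 0 & nz < d[3]
      cand <- 1L + nx[ok] + d[1] * (ny[ok] + d[2] * nz[ok])
      cand <- cand[mask[cand] & labels[cand] == 0L]
      if (length(cand)) {
        labels[cand] <- nxt
        stack <- c(stack, cand)
      }
    }
  }
  labels
}
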