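#' Normalise a fundamental-domain embedding to the standard strip frame
#'
#' The flat development of the twice-slit surface is oriented by a
#' similarity transform (rotation + translation + uniform positive scale,
#' never a reflection) so that the inter-feature slit boundary lies on the
#' imaginary axis spanning exactly `[0, 2*pi]` and the surface occupies
#' non-positive real coordinates, with the distal boundary parallel to the
#' axis on the far left. The transform is `z -> (z - z0) * 2*pi*i / (z1 -
#' z0)` with the slit endpoints as anchors; the endpoint assignment is
#' chosen so the domain lands in the left half-plane, which keeps face
#' orientation positive.
#'
#' @param embedding a `PlanarEmbedding` of the cut fundamental domain.
#' @param slit_chain integer vertex chain (ids on the embedding) running
#'   along the slit boundary from one endpoint to the other.
#' @param straight_tol tolerance for verifying the slit chain is straight,
#'   relative to its length.
#' @return a `PlanarEmbedding` with `domain = "strip"`; `extra$slit_chain`
#'   and `extra$slit_param` record the chain and its imaginary coordinates.
#' @export
normalise_strip <- function(embedding, slit_chain, straight_tol = 1e-4) {
  pts <- embedding$points
  ch <- pts[slit_chain]
  z0 <- ch[1]
  z1 <- ch[length(ch)]
  if (abs(z1 - z0) == 0) stop("geometry error: slit endpoints coincide")
  # collinearity check: the flat metric makes the slit boundary straight
  dev <- abs(Im(Conj(z1 - z0) * (ch - z0))) / abs(z1 - z0)
  if (max(dev) > straight_tol * abs(z1 - z0))
    stop("geometry error: slit boundary is not straight in the development ",
         "(max deviation ", signif(max(dev), 3), ")")
  map <- function(p, a, b) (p - a) * (2i * pi) / (b - a)
  new <- map(pts, z0, z1)
  if (mean(Re(new)) > 0) new <- map(pts, z1, z0)
  out <- embedding
  out$points <- new
  out$domain <- "strip"
  out$extra$slit_chain <- slit_chain
  out$extra$slit_param <- Im(out$points[slit_chain])
  sa <- embedding_signed_areas(out$points, out$faces)
  if (any(sa <= 0)) stop("geometry error: strip normalisation flipped faces")
  out
}

#' Exponential map from the strip to the annulus
#'
#' Applies `z -> exp(z)` per vertex. The slit boundary (real part 0,
#' imaginary part in `[0, 2*pi]`) maps onto the unit circle and the distal
#' boundary onto an inner concentric circle of radius `exp(min(Re(z)))`.
#'
#' @param strip a normalised strip `PlanarEmbedding`.
#' @return a `PlanarEmbedding` with `domain = "annulus"`.
#' @export
exponential_map <- function(strip) {
  stopifnot(inherits(strip, "PlanarEmbedding"))
  if (strip$domain != "strip")
    stop("exponential_map expects a normalised strip embedding")
  out <- strip
  out$points <- exp(strip$points)
  out$domain <- "annulus"
  out
}
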