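# Shared fixture builders; everything is generated in code, nothing on disk.

# small valid patch table (areas m^2, perimeters >= circle bound)
makePatchDf <- function(n = 10, seed = 1) {
  set.seed(seed)
  area <- runif(n, 3000, 9e5)
  s <- 1 + rlnorm(n, -2, 0.8)
  data.frame(id = sprintf("p%02d", seq_len(n)),
             x = runif(n, 4e5, 4.2e5), y = runif(n, 6.4e6, 6.42e6),
             area = area, perimeter = s * 2 * sqrt(pi * area))
}

makePatches <- function(n = 10, seed = 1) patchSet(makePatchDf(n, seed))

# tiny climate cube with controllable noise/anomaly via syntheticConfig
smallConfig <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(domainWidth = 30000, domainHeight = 4000,
                   nParents = 15, meanOffspring = 4)
  for (nm in names(defaults))
    if (!nm %in% names(args)) args[[nm]] <- defaults[[nm]]
  do.call(syntheticConfig, c(list(seed = seed), args))
}

# GeoJSON writers for polygon / flightline fixtures
writePolygonGeojson <- function(rings, path, ids = NULL) {
  feats <- lapply(seq_along(rings), function(i) {
    ring <- rings[[i]]
    if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ])))
      ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(id = if (is.null(ids)) as.character(i)
                           else ids[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(k) as.list(ring[k, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}
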