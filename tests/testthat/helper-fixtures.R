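## Shared, lazily built heavy fixtures (one transport factorization etc.
## reused across test files).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!is.null(.fixtures[[name]])) return(.fixtures[[name]])
  .fixtures[[name]] <- switch(name,
    fbr100 = buildPhantom(collagenThickness = 100),
    grid100 = buildPhantomGrid(fixture("fbr100")),
    ts100 = transportSystem(fixture("grid100")),
    refs = referenceIntensities(
      syntheticReferences(generatorSpec(noise = FALSE))),
    modelPoint = {
      m <- snrModel(pointSource(), fixture("fbr100"),
                    grid = fixture("grid100"), refs = fixture("refs"))
      m@cache$ts <- fixture("ts100")
      m
    },
    Epoint = solveFluence(fixture("ts100"), pointSource()),
    surfPoint11 = snrSurface(fixture("modelPoint"), n = 11),
    surfPoint21 = snrSurface(fixture("modelPoint"), n = 21),
    stop("unknown fixture: ", name))
  .fixtures[[name]]
}
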