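# shared helpers for micro-scale engine runs

# a single fully specified islet tissue: disk of radius r at (cx, cy) with a
# strength-S ring, on a W x H grid
microIsletTissue <- function(W = 30, H = 30, cx = 15, cy = 15, r = 5,
                             strength = 1440) {
  i1 <- insulitisSim:::.fixtureIslet(cx, cy, r, 1L)
  insulitisSim:::.syntheticTissue(W, H, betaSites = i1$beta,
                                  interiorSites = i1$beta,
                                  membraneSites = i1$ring,
                                  strength = strength)
}

# run the compiled engine on an explicit tissue/cell state
runEngine <- function(tissue, cells, config, ticks, recordEvery = ticks,
                      triggered = NULL, checkInvariants = TRUE,
                      returnState = TRUE) {
  st <- insulitisSim:::.engineState(tissue, cells, triggered = triggered)
  raw <- insulitisSim:::.cpp_run(st, insulitisSim:::.engineParams(config),
                                 nTicks = as.integer(ticks),
                                 recordEvery = as.integer(recordEvery),
                                 checkInvariants = checkInvariants,
                                 returnState = returnState, earlyStop = FALSE)
  if (returnState)
    raw$state <- insulitisSim:::.fromEngineState(raw$state, tissue)
  raw
}

# membrane values of a dumped engine state, NA outside rings
memValues <- function(state) state$mem[!is.na(state$mem)]
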