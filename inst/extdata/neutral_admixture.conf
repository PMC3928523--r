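# Neutral admixture between two populations connected by symmetric
# migration (island model).  No trait modules; the default identity
# fitness gives every individual the same reproductive weight.

Chromosomes chroms
    lengths = 50000000

Trajectory_Constant popsize
    value = 100

Trajectory_Constant mig
    value = 0.05

Demography demo
    populations = 2
    generations = 20
    size = popsize
    migration = island
    migration_rate = mig

RecombinationMap_Uniform map
    rate = 1

Locus marker
    chromosome = 1
    position = 25000000
    frequency = 0.5

Simulator sim
    seed = 11
    chromosomes = chroms
    demography = demo
    maps = map
    loci = marker
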