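# CSV schema

All files UTF-8, comma-separated, header row, ISO-8601 timestamps.

## Inputs (one experiment directory)

### tanks.csv
| column     | type   | values / units                      |
|------------|--------|-------------------------------------|
| tank_id    | string | e.g. `T01`                          |
| population | enum   | `eukaryote`, `mixed`                |
| treatment  | enum   | `heated`, `reference`               |
| replicate  | int    | 1-3                                 |

### sensors.csv
| column    | type     | values / units                               |
|-----------|----------|----------------------------------------------|
| tank_id   | string   |                                              |
| timestamp | datetime | `YYYY-MM-DDTHH:MM:SS` (local, minute resolution) |
| variable  | enum     | `temperature` (degC), `irradiance` (umol photons m-2 s-1) |
| value     | numeric  | variable's units                             |

Timestamps are strictly increasing per (tank, variable); cadence as fine as
10 min. Day 0 = earliest sensor date (inoculation day).

### counts.csv
| column    | type | units          |
|-----------|------|----------------|
| tank_id   | str  |                |
| day       | int  | experiment day |
| replicate | int  | 1-3            |
| count     | num  | cells mL-1     |

### samples.csv
| column  | type | units       | meaning                      |
|---------|------|-------------|------------------------------|
| tank_id | str  |             |                              |
| day     | int  |             |                              |
| PC      | num  | umol C L-1  | particulate carbon           |
| PN      | num  | umol N L-1  | particulate nitrogen         |
| PP      | num  | umol P L-1  | particulate phosphorus       |
| chl_a   | num  | ug L-1      | chlorophyll-a                |
| TDN     | num  | umol N L-1  | total dissolved nitrogen     |
| TDP     | num  | umol P L-1  | total dissolved phosphorus   |
| SRP     | num  | umol P L-1  | soluble reactive phosphorus  |

Derived ratios (N:C = PN/PC, P:C = PP/PC, N:P = PN/PP, mol mol-1) are
computed only where both operands are present and the denominator positive.

## Outputs

### forcing.csv
One row per retained (tank, day): `tank_id`, `population`, `treatment`,
`day`, `T_C` (degC, morning-window mean), `I` (umol photons m-2 s-1,
morning-window mean), `mu` (d-1, count-derived), `limitation`.

### predictions.csv / stoichiometry_comparison.csv
One row per (tank, day): stoichiometry `NC`, `PC`, `NP` (mol mol-1), `ChlC`
(dimensionless), `feasible` flag, and allocation fractions in columns
`<element>_<pool>` with element in {C, N, P} and pool in {biosynthetic,
photosynthetic, C_storage, N_storage, essential}.

### allocation.csv
Long format: `tank_id`, `day`, `element`, `pool`, `fraction`
(dimensionless fraction of that element's cellular total).
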