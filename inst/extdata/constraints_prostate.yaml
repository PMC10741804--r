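# Planning dose constraints, 6000 cGy / 20 fx prostate plan.
# The single femoral-head row of the protocol is expanded to both sides.
site: prostate
prescription_cGy: 6000
constraints:
  - {structure: PTV, statistic: Dmin, direction: at-least, limit: 5700}
  - {structure: PTV, statistic: Dmax, direction: at-most, limit: 6420}
  - {structure: Rectum, statistic: V4500cGy, direction: at-most, limit: 15}
  - {structure: Rectum, statistic: V2800cGy, direction: at-most, limit: 35}
  - {structure: Rectum, statistic: V900cGy, direction: at-most, limit: 80}
  - {structure: Bladder, statistic: V4500cGy, direction: at-most, limit: 25}
  - {structure: Bladder, statistic: V2800cGy, direction: at-most, limit: 50}
  - {structure: Anal Canal, statistic: V4500cGy, direction: at-most, limit: 15}
  - {structure: Anal Canal, statistic: V2800cGy, direction: at-most, limit: 35}
  - {structure: Anal Canal, statistic: V900cGy, direction: at-most, limit: 80}
  - {structure: Femur Right, statistic: V3100cGy, direction: at-most, limit: 1}
  - {structure: Femur Left, statistic: V3100cGy, direction: at-most, limit: 1}
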