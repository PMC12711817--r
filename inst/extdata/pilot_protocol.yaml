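# Structured trial protocol for the pilot relative-bioavailability study:
# five top-level critical safety factors (four subjective, one objective),
# their measurement procedures, and stratified safe domains/states.
protocol_id: pilot-bioavailability-01
cycle: 1
sponsor_meta: "Sponsor and site identifiers withheld (LOCAL storage only)."
factors:
  - id: F1
    group: F1
    name: Blood pressure
    kind: subjective
    unit: mmHg
    safety_critical: true
    harm_direction: both
    checkable: true
  - id: F2
    group: F2
    name: Heart rate
    kind: subjective
    unit: b/min
    safety_critical: true
    harm_direction: high
    checkable: true
  - id: F3.1
    group: F3
    name: Blood sugar (fasting)
    kind: subjective
    unit: mg/dL
    safety_critical: true
    harm_direction: high
    checkable: true
  - id: F3.2
    group: F3
    name: Blood sugar (30 min before meal)
    kind: subjective
    unit: mg/dL
    safety_critical: true
    harm_direction: both
    checkable: true
  - id: F3.3
    group: F3
    name: Blood sugar (60 min after meal)
    kind: subjective
    unit: mg/dL
    safety_critical: true
    harm_direction: high
    checkable: true
  - id: F3.4
    group: F3
    name: Blood sugar (bedtime)
    kind: subjective
    unit: mg/dL
    safety_critical: true
    harm_direction: both
    checkable: true
  - id: F4
    group: F4
    name: Stay in bed
    kind: subjective
    unit: min
    safety_critical: true
    harm_direction: low
    checkable: false
  - id: F5
    group: F5
    name: Ambient temperature
    kind: objective
    unit: "degC"
    safety_critical: true
    harm_direction: both
    checkable: true
procedures:
  - factor: F1
    schedule: "Every 30 min / 24 h"
    phase: both
    constraints:
      - "Breakfast: 8:00-8:30"
      - "Lunch: 12:00-13:00"
      - "Dinner: 18:00-18:40"
  - factor: F2
    schedule: "Every 15 min / 24 h"
    phase: both
    constraints:
      - "Male: walking max 60 min / 24 h"
      - "Female: walking max 50 min / 24 h"
      - "Watch TV: max 30 min (no action)"
      - "Use phone: max 30 min"
  - factor: F3.1
    schedule: "Fasting"
    phase: both
    constraints: ["Breakfast < 1100 calorie"]
  - factor: F3.2
    schedule: "30 min before meal"
    phase: both
    constraints: ["Lunch < 1200 calorie"]
  - factor: F3.3
    schedule: "60 min after meal"
    phase: both
    constraints: ["Dinner < 800 calorie"]
  - factor: F3.4
    schedule: "Bedtime"
    phase: both
    constraints: []
  - factor: F4
    schedule: "Before administration"
    phase: before
    constraints: ["Sleep style: Stargazer or Skydiver"]
  - factor: F4
    schedule: "After administration"
    phase: after
    constraints: ["Sleep style: Stargazer or Skydiver"]
  - factor: F5
    schedule: "Every 30 min / 24 h"
    phase: both
    constraints: []
domains:
  - factor: F1
    phase: any
    state_kind: interval
    bands:
      - {lower: 80, upper: 130}
  - factor: F2
    phase: any
    state_kind: interval
    bands:
      - {age_max: 39, lower: 90, upper: 153}
      - {age_min: 41, age_max: 45, lower: 88, upper: 149}
      - {age_min: 46, age_max: 50, lower: 80, upper: 145}
      - {age_min: 51, age_max: 55, lower: 83, upper: 140}
      - {age_min: 56, age_max: 60, lower: 80, upper: 136}
      - {age_min: 61, age_max: 65, lower: 78, upper: 132}
  - factor: F3.1
    phase: any
    state_kind: interval
    bands:
      - {upper: 100, upper_inclusive: false}
  - factor: F3.2
    phase: any
    state_kind: interval
    bands:
      - {lower: 70, upper: 130}
  - factor: F3.3
    phase: any
    state_kind: interval
    bands:
      - {upper: 180, upper_inclusive: false}
  - factor: F3.4
    phase: any
    state_kind: interval
    bands:
      - {lower: 100, upper: 140}
  - factor: F4
    phase: any
    state_kind: duration_minimum
    bands:
      - {phase: before, lower: 60}
      - {phase: after, lower: 240}
  - factor: F5
    phase: any
    state_kind: interval
    bands:
      - {lower: 19, upper: 25}
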