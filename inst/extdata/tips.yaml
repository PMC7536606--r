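# Tip bank: caregiving diet tips, tagged by category and ADRD stage.
# Each tip is written at three education tiers.
tips:
  - id: pd1
    category: proper_diet
    stages: [any]
    text:
      basic: "Offer vegetables, berries and fish often. Keep sweets and fried food rare."
      standard: "Build meals around vegetables, berries, whole grains and fish, and keep butter, cheese, red meat and sweets occasional."
      advanced: "Follow the MIND pattern: daily vegetables and whole grains, berries and fish weekly, olive oil as the main fat; restrict butter, cheese, red meat, fried food and pastries to occasional servings."
  - id: pd2
    category: proper_diet
    stages: [early]
    text:
      basic: "Keep regular meal times. Eat together when you can."
      standard: "Keep a steady routine of three meals a day at familiar times; shared meals encourage better eating."
      advanced: "A consistent three-meal schedule supports appetite regulation in early-stage ADRD; target roughly even energy distribution across meals."
  - id: pd3
    category: proper_diet
    stages: [middle, late]
    text:
      basic: "Serve small portions more often. Make food easy to eat."
      standard: "Offer smaller, more frequent meals and finger foods that are easy to handle."
      advanced: "As ADRD progresses, divide the daily energy requirement over 4-6 small servings and favor bite-sized, self-feedable textures to maintain intake."
  - id: pd4
    category: proper_diet
    stages: [any]
    text:
      basic: "Give water through the day, not just at meals."
      standard: "Encourage fluids across the whole day; thirst awareness declines with dementia."
      advanced: "Schedule fluids between meals (about 6-8 cups daily) since thirst perception is blunted in ADRD; soups and fruit count toward intake."
  - id: ec1
    category: eating_challenge
    stages: [any]
    text:
      basic: "Stay calm. Offer the meal again a little later."
      standard: "If a meal is refused, stay calm and offer it again after a short break instead of insisting."
      advanced: "Meal refusal is common and usually transient: remove distractions, re-offer after 15-30 minutes, and log refusals to spot patterns rather than confronting in the moment."
  - id: ec2
    category: eating_challenge
    stages: [middle]
    text:
      basic: "Put one food on the plate at a time."
      standard: "Serve one food at a time on a plain plate; too many choices can overwhelm."
      advanced: "In middle-stage ADRD, simplify the visual field: one high-contrast food per plain plate reduces decision load and improves intake."
  - id: ec3
    category: eating_challenge
    stages: [middle, late]
    text:
      basic: "Use cups and spoons that are easy to hold."
      standard: "Adaptive utensils, lidded cups and plate guards help keep mealtimes independent."
      advanced: "Introduce adaptive utensils before fine-motor decline forces feeding assistance; preserved self-feeding correlates with better energy intake."
  - id: ec4
    category: eating_challenge
    stages: [early]
    text:
      basic: "Let him help with cooking. It builds appetite."
      standard: "Involve him in simple meal preparation; familiar kitchen tasks stimulate appetite and preserve skills."
      advanced: "In early-stage ADRD, structured participation in meal preparation sustains procedural memory and is associated with improved mealtime engagement."
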