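# 42-attribute pedestrian appearance schema with source-label coalescing.
#
# Three pedestrian-attribute (PAI) source networks, each trained on a
# different dataset (pa100k, peta, rap), emit per-label probabilities.
# Source labels are coalesced onto 42 movement-relevant target attributes
# grouped into 8 categories; appearance-only labels that cannot plausibly
# be estimated from movement (hats, glasses, hair, patterns, ...) are
# explicitly dropped.  Per-target "mode" controls how multiple mapped
# source scores combine: "average" (arithmetic mean, used when the sources
# measure the same concept) or "max" (union semantics, used when sources
# partition a broader concept).
version: 1
groups:
  Gender: [Female, Male]
  AgeGroup: [AgeChild, AgeYoungAdult, AgeAdult, AgeElderly]
  BodyType: [BodyFat, BodyNormal, BodyThin]
  Viewpoint: [Front, Side, Back]
  CarryConditions: [Backpack, HandBag, ShoulderBag, PlasticBags,
                    HoldObjectsInFront, CarryingOther, NoCarrying]
  Clothing: [ShortSleeve, LongSleeve, TShirt, Shirt, Jacket, LongCoat,
             FormalWear, CasualWear, Jeans, Trousers, Shorts, SkirtDress]
  Footwear: [LeatherShoes, SportShoes, CasualShoes, ClothShoes, Boots, Sandals]
  ApparentAction: [Calling, Talking, Gathering, Pushing, Pulling]
modes:
  AgeChild: average
  FormalWear: max
  CasualWear: max
  SkirtDress: max
  CarryingOther: max
  default: average
sources:
  pa100k:
    Female: Female
    AgeOver60: AgeElderly
    Age18-60: AgeAdult
    AgeLess18: AgeChild
    Front: Front
    Side: Side
    Back: Back
    Hat: DROP
    Glasses: DROP
    HandBag: HandBag
    ShoulderBag: ShoulderBag
    Backpack: Backpack
    HoldObjectsInFront: HoldObjectsInFront
    ShortSleeve: ShortSleeve
    LongSleeve: LongSleeve
    UpperStride: DROP
    UpperLogo: DROP
    UpperPlaid: DROP
    UpperSplice: DROP
    LowerStripe: DROP
    LowerPattern: DROP
    LongCoat: LongCoat
    Trousers: Trousers
    Shorts: Shorts
    Skirt&Dress: SkirtDress
    Boots: Boots
  peta:
    Age16-30: AgeYoungAdult
    Age31-45: AgeAdult
    Age46-60: AgeAdult
    AgeAbove61: AgeElderly
    Backpack: Backpack
    CarryingOther: CarryingOther
    CasualLower: CasualWear
    CasualUpper: CasualWear
    FormalLower: FormalWear
    FormalUpper: FormalWear
    Hat: DROP
    Jacket: Jacket
    Jeans: Jeans
    LeatherShoes: LeatherShoes
    Logo: DROP
    LongHair: DROP
    Male: Male
    MessengerBag: ShoulderBag
    Muffler: DROP
    NoAccessory: DROP
    NoCarrying: NoCarrying
    Plaid: DROP
    PlasticBags: PlasticBags
    Sandals: Sandals
    Shoes: CasualShoes
    Shorts: Shorts
    ShortSleeve: ShortSleeve
    Skirt: SkirtDress
    Sneaker: SportShoes
    Stripes: DROP
    Sunglasses: DROP
    Trousers: Trousers
    TShirt: TShirt
    UpperOther: DROP
    V-Neck: DROP
  rap:
    Female: Female
    AgeLess16: AgeChild
    Age17-30: AgeYoungAdult
    Age31-45: AgeAdult
    BodyFat: BodyFat
    BodyNormal: BodyNormal
    BodyThin: BodyThin
    Customer: DROP
    Clerk: DROP
    BaldHead: DROP
    LongHair: DROP
    BlackHair: DROP
    Hat: DROP
    Glasses: DROP
    Muffler: DROP
    Shirt: Shirt
    Sweater: DROP
    Vest: DROP
    TShirt: TShirt
    Cotton: DROP
    Jacket: Jacket
    Suit-Up: FormalWear
    Tight: DROP
    ShortSleeve: ShortSleeve
    LongTrousers: Trousers
    Skirt: SkirtDress
    ShortSkirt: SkirtDress
    Dress: SkirtDress
    Jeans: Jeans
    TightTrousers: DROP
    LeatherShoes: LeatherShoes
    SportShoes: SportShoes
    Boots: Boots
    ClothShoes: ClothShoes
    CasualShoes: CasualShoes
    Backpack: Backpack
    SSBag: ShoulderBag
    HandBag: HandBag
    Box: CarryingOther
    PlasticBags: PlasticBags
    PaperBag: CarryingOther
    HandTrunk: CarryingOther
    OtherAttachment: CarryingOther
    Calling: Calling
    Talking: Talking
    Gathering: Gathering
    Holding: HoldObjectsInFront
    Pushing: Pushing
    Pulling: Pulling
    CarryingByArm: CarryingOther
    CarryingByHand: CarryingOther
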