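ACE
AGE
AIM
AIR
AND
ANT
APE
ARM
ART
ASK
BAG
BAR
BAT
BED
BEE
BIG
BIT
BOX
BOY
BUS
CAB
CAN
CAP
CAR
CAT
COW
CUP
CUT
DAY
DEN
DOG
DOT
EAR
EAT
EGG
END
EYE
FAN
FAR
FIT
FIX
FLY
FOX
FUN
GAP
GAS
GEM
GET
GO
GUM
HAT
HEN
HIT
HOT
ICE
INK
JAM
JAR
JOY
KEY
KIT
LAP
LEG
LET
LID
LIP
LOG
LOT
LOW
MAN
MAP
MAT
MIX
MUD
NET
NEW
NOD
NOW
NUT
OAK
ODD
OIL
OLD
ONE
OWL
PAN
PEN
PET
PIE
PIG
PIN
POT
RAT
RAW
RED
RIB
RIM
ROW
RUG
RUN
SAD
SEA
SEE
SET
SIT
SIX
SKY
SON
SUN
TAP
TEA
TEN
TIE
TIN
TIP
TOE
TOP
TOY
TWO
VAN
WAR
WAX
WEB
WET
WIN
YES
ZOO
ABLE
ACID
AREA
BABY
BAND
BANK
BARN
BEAR
BELL
BEST
BIRD
BLUE
BOAT
BONE
BOOK
CAKE
CALM
CARD
CARE
CASE
CITY
CLAY
COAT
COLD
CORN
DARK
DEAR
DEEP
DEER
DESK
DOOR
DUST
EAST
EASY
FACE
FARM
FAST
FIRE
FISH
FLAG
FOOD
FOOT
FORM
FREE
FROG
GAME
GATE
GIFT
GOLD
GOOD
HAND
HERO
HILL
HOME
HOPE
IDEA
IRON
KIND
KING
LAKE
LAMP
LAND
LEAF
LIFE
LINE
LION
LIST
LOVE
MAIL
MILK
MIND
MOON
NAME
NEST
NICE
NOTE
OPEN
PAGE
PARK
PATH
PLAN
PLAY
RAIN
RICE
RING
ROAD
ROCK
ROOM
ROSE
SAFE
SALT
SAND
SEAT
SHIP
SHOE
SNOW
SONG
STAR
TIME
TREE
WARM
WAVE
WEST
WIND
WING
WISH
WOOD
WORD
YEAR
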